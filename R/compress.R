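#' Proportional compression of diagnosis counts
#'
#' Routine facility data record several clinical diagnoses per consultation,
#' so per cluster-month the diagnosis-category counts can exceed the all-cause
#' consultation total. Compression rescales each record's category counts
#' proportionally so they sum to exactly 100% of all-cause consultations,
#' integerised by largest-remainder apportionment (ties broken by category
#' order). Records with consultations but no recorded diagnoses keep zero
#' category counts and are tallied in the attached data-quality report.
#'
#' @param records data.frame in the [simulate_trial()] schema (or any frame
#'   with the category columns and `all_cause`).
#' @param categories category column names.
#' @return records with compressed counts; attribute `"data_quality"` is a
#'   list with `n_zero_diagnosis` (records with `all_cause > 0` but no
#'   recorded diagnoses) and `n_records`.
#' @examples
#' rec <- data.frame(malaria = 60, lrti = 40, other = 100, all_cause = 100)
#' compress_counts(rec, c("malaria", "lrti", "other"))
#' @export
compress_counts <- function(records, categories = record_categories(records)) {
  cnt <- as.matrix(records[, categories, drop = FALSE])
  if (any(cnt < 0) || any(records$all_cause < 0)) {
    stop("negative counts are not allowed")
  }
  n_zero <- 0L
  for (i in seq_len(nrow(records))) {
    ac <- records$all_cause[i]
    s <- sum(cnt[i, ])
    if (s == 0) {
      if (ac > 0) n_zero <- n_zero + 1L
      cnt[i, ] <- 0L
      next
    }
    cnt[i, ] <- apportion_largest_remainder(cnt[i, ], ac)
  }
  if (n_zero > 0) {
    warning(sprintf("%d record(s) with consultations but no recorded diagnoses; category counts left at zero", n_zero))
  }
  records[, categories] <- cnt
  attr(records, "data_quality") <- list(n_zero_diagnosis = n_zero,
                                        n_records = nrow(records))
  records
}

#' Mean diagnosis multiplicity
#'
#' Average number of recorded diagnoses per consultation over a set of
#' records: the ratio of summed category counts to summed all-cause
#' consultations.
#'
#' @param records data.frame of cluster-month records.
#' @param arm optional arm label to filter on.
#' @param window optional integer vector of `month_index` values to keep.
#' @param categories category column names.
#' @return a single ratio.
#' @export
mean_multiplicity <- function(records, arm = NULL, window = NULL,
                              categories = record_categories(records)) {
  if (!is.null(arm)) records <- records[records$arm == arm, , drop = FALSE]
  if (!is.null(window)) {
    records <- records[records$month_index %in% window, , drop = FALSE]
  }
  if (nrow(records) == 0) stop("no records in the selected window")
  tot <- sum(records$all_cause)
  if (tot == 0) stop("zero consultations in the selected window")
  sum(records[, categories]) / tot
}
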