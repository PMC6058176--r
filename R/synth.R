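#' Trial design configuration for the synthetic facility-data generator
#'
#' Builds the configuration object consumed by [simulate_trial()]. Defaults
#' emulate the Burkina Faso mass-radio cluster-randomised trial: 7 matched
#' pairs of rural clusters (14 clusters, two arms), monthly under-five
#' consultation counts from January 2011 to December 2014 (48 months), six
#' clinical diagnosis categories, a 35-month campaign starting March 2012
#' split into three campaign years, and diagnosis multiplicity (diagnoses per
#' consultation) rising linearly over the study window.
#'
#' @param n_pairs number of matched cluster pairs (>= 2).
#' @param start_year,start_month first calendar month of the study window.
#' @param n_months number of consecutive months.
#' @param period_breaks named integer vector giving the first month index
#'   (0-based) of each campaign period after baseline, e.g.
#'   `c(year1 = 14, year2 = 26, year3 = 38)`. Months before the first break
#'   are baseline.
#' @param categories character vector of diagnosis-category labels.
#' @param baseline_rate expected monthly diagnosis count (all categories
#'   summed) per cluster at month 0, before arm/cluster/seasonal terms.
#' @param category_mix proportions per category, summing to 1.
#' @param trend log-scale secular trend per month.
#' @param season numeric(12) log-scale month-of-year effects.
#' @param arm_offset log-scale systematic baseline difference of the
#'   intervention arm.
#' @param confounder_effect log-scale coefficient per unit of the cluster
#'   confounder score.
#' @param cluster_sd standard deviation of log-scale cluster random
#'   intercepts.
#' @param true_effects matrix of true intervention-arm rate ratios with one
#'   row per category and columns `year1`, `year2`, `year3`; 1 means no
#'   effect.
#' @param multiplicity_path list with elements `control` and `intervention`,
#'   each `c(start, end)` average diagnoses per consultation, interpolated
#'   linearly over the window.
#' @param seed optional integer RNG seed stored with the design.
#' @return an object of class `trial_design`.
#' @seealso [simulate_trial()], [inject_multiplicity()]
#' @export
trial_design <- function(n_pairs = 7,
                         start_year = 2011, start_month = 1,
                         n_months = 48,
                         period_breaks = c(year1 = 14, year2 = 26, year3 = 38),
                         categories = c("malaria", "lrti", "diarrhoea",
                                        "urti", "malnutrition", "other"),
                         baseline_rate = 1000,
                         category_mix = c(malaria = 0.55, lrti = 0.18,
                                          diarrhoea = 0.03, urti = 0.10,
                                          malnutrition = 0.04, other = 0.10),
                         trend = 0.005,
                         season = 0.3 * cos(2 * pi * ((1:12) - 9) / 12),
                         arm_offset = 0.1,
                         confounder_effect = 0.2,
                         cluster_sd = 0.25,
                         true_effects = default_true_effects(categories),
                         multiplicity_path = list(control = c(1.23, 2.17),
                                                  intervention = c(1.51, 2.29)),
                         seed = NULL) {
  stopifnot(n_pairs >= 2, n_months >= 1, baseline_rate > 0, cluster_sd >= 0)
  categories <- as.character(categories)
  if (length(category_mix) != length(categories)) {
    stop("category_mix must have one entry per category")
  }
  if (abs(sum(category_mix) - 1) > 1e-9) {
    stop("category_mix must sum to 1")
  }
  if (length(season) != 12) stop("season must have 12 entries")
  if (is.null(dim(true_effects))) {
    stop("true_effects must be a category x period matrix")
  }
  true_effects <- as.matrix(true_effects)
  if (!all(rownames(true_effects) == categories) ||
      !identical(colnames(true_effects), c("year1", "year2", "year3"))) {
    stop("true_effects must have categories as rows and year1..year3 columns")
  }
  if (any(true_effects <= 0)) stop("all rate ratios must be positive")
  if (any(unlist(multiplicity_path) < 1)) {
    stop("multiplicity values must be >= 1")
  }
  if (any(period_breaks < 1) || any(period_breaks > n_months)) {
    stop("period_breaks must lie inside the month range")
  }
  months <- month_table(start_year, start_month, n_months)
  structure(
    list(n_pairs = n_pairs, months = months,
         period_breaks = period_breaks, categories = categories,
         baseline_rate = baseline_rate,
         category_mix = stats::setNames(as.numeric(category_mix), categories),
         trend = trend, season = season, arm_offset = arm_offset,
         confounder_effect = confounder_effect, cluster_sd = cluster_sd,
         true_effects = true_effects,
         multiplicity_path = multiplicity_path, seed = seed),
    class = "trial_design")
}

#' Default true intervention effects
#'
#' Rate ratios matching the utilisation effects estimated in the Burkina Faso
#' trial: malaria 1.56/1.37/1.35, lower respiratory infections
#' 1.39/1.25/1.11, diarrhoea 1.73/1.60/2.07 across campaign years 1-3;
#' non-targeted categories have no effect.
#'
#' @param categories category labels (rows of the returned matrix).
#' @return matrix of rate ratios, categories x (year1, year2, year3).
#' @export
default_true_effects <- function(categories = c("malaria", "lrti", "diarrhoea",
                                                "urti", "malnutrition",
                                                "other")) {
  eff <- matrix(1, nrow = length(categories), ncol = 3,
                dimnames = list(categories, c("year1", "year2", "year3")))
  if ("malaria" %in% categories) eff["malaria", ] <- c(1.56, 1.37, 1.35)
  if ("lrti" %in% categories) eff["lrti", ] <- c(1.39, 1.25, 1.11)
  if ("diarrhoea" %in% categories) eff["diarrhoea", ] <- c(1.73, 1.60, 2.07)
  eff
}

# calendar month table: month_index (0-based), year, month-of-year
month_table <- function(start_year, start_month, n_months) {
  idx <- seq_len(n_months) - 1L
  total <- (start_year * 12L + (start_month - 1L)) + idx
  data.frame(month_index = idx,
             year = total %/% 12L,
             month = total %% 12L + 1L)
}

# period label per month index, from the 0-based break table
period_labels <- function(month_index, period_breaks) {
  breaks <- sort(period_breaks)
  lab <- rep("baseline", length(month_index))
  for (p in names(breaks)) lab[month_index >= breaks[[p]]] <- p
  factor(lab, levels = c("baseline", names(breaks)))
}

# linear interpolation of the diagnoses-per-consultation path over the window
interp_multiplicity <- function(path, month_index, n_months) {
  if (n_months == 1) return(rep(path[1], length(month_index)))
  path[1] + (path[2] - path[1]) * month_index / (n_months - 1)
}

#' Simulate a cluster-randomised facility-utilisation dataset
#'
#' Draws monthly diagnosis counts per cluster and category from a Poisson law
#' whose log-mean combines the baseline rate and category share, a linear
#' secular trend, month-of-year seasonality, a systematic arm offset, a
#' cluster-level confounder score, a normal cluster random intercept, and the
#' configured true rate ratio when the month falls in a campaign period and
#' the cluster is in the intervention arm. The all-cause consultation total is
#' derived by dividing the summed diagnosis counts by the arm's interpolated
#' diagnosis multiplicity for that month (so diagnosis counts may exceed
#' consultations, as in routine data where one child receives several
#' diagnoses per visit).
#'
#' @param design a [trial_design()] object.
#' @param seed integer seed; overrides `design$seed`. The same seed yields a
#'   byte-identical dataset.
#' @return data.frame with one row per cluster-month: `cluster_id`,
#'   `pair_id`, `arm` (`"control"`/`"intervention"`), `confounder_score`,
#'   `year`, `month`, `month_index`, `period`, one count column per category,
#'   and `all_cause`.
#' @export
simulate_trial <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "trial_design"))
  with_seed(seed, {
    n_cl <- 2L * design$n_pairs
    cl <- data.frame(
      cluster_id = sprintf("c%02d", seq_len(n_cl)),
      pair_id = rep(seq_len(design$n_pairs), each = 2L),
      arm = rep(c("control", "intervention"), design$n_pairs),
      confounder_score = stats::rnorm(n_cl),
      stringsAsFactors = FALSE)
    cl$intercept <- stats::rnorm(n_cl, 0, design$cluster_sd)

    mt <- design$months
    n_m <- nrow(mt)
    grid <- merge(cl, mt, by = NULL)
    grid <- grid[order(grid$cluster_id, grid$month_index), ]
    grid$period <- period_labels(grid$month_index, design$period_breaks)

    is_int <- grid$arm == "intervention"
    base_lp <- design$trend * grid$month_index +
      design$season[grid$month] +
      design$arm_offset * is_int +
      design$confounder_effect * grid$confounder_score +
      grid$intercept

    counts <- matrix(0L, nrow(grid), length(design$categories),
                     dimnames = list(NULL, design$categories))
    for (cat in design$categories) {
      log_rr <- rep(0, nrow(grid))
      for (p in colnames(design$true_effects)) {
        hit <- is_int & grid$period == p
        log_rr[hit] <- log(design$true_effects[cat, p])
      }
      lambda <- exp(log(design$baseline_rate * design$category_mix[[cat]]) +
                      base_lp + log_rr)
      counts[, cat] <- stats::rpois(nrow(grid), lambda)
    }

    mult <- ifelse(is_int,
                   interp_multiplicity(design$multiplicity_path$intervention,
                                       grid$month_index, n_m),
                   interp_multiplicity(design$multiplicity_path$control,
                                       grid$month_index, n_m))
    all_cause <- as.integer(round_half_away(rowSums(counts) / mult))

    out <- data.frame(grid[, c("cluster_id", "pair_id", "arm",
                               "confounder_score", "year", "month",
                               "month_index", "period")],
                      counts, all_cause = all_cause,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Inflate diagnosis counts to follow a multiplicity path
#'
#' Rescales each record's category counts so that the ratio of summed
#' diagnosis counts to all-cause consultations follows the linear
#' interpolation of the arm's start-to-end diagnoses-per-consultation
#' averages. Inflation is allocated proportionally to the existing counts and
#' integerised by largest-remainder apportionment. Records with zero
#' consultations (or zero recorded diagnoses) pass through unchanged.
#'
#' @param records data.frame in the [simulate_trial()] schema.
#' @param multiplicity_path list with `control` and `intervention` elements,
#'   each `c(start, end)` with values >= 1.
#' @param categories category columns; defaults to the columns between
#'   `period` and `all_cause`.
#' @return records with inflated category counts.
#' @export
inject_multiplicity <- function(records, multiplicity_path,
                                categories = record_categories(records)) {
  if (any(unlist(multiplicity_path) < 1)) {
    stop("multiplicity values must be >= 1")
  }
  n_m <- max(records$month_index) + 1L
  cnt <- as.matrix(records[, categories, drop = FALSE])
  for (i in seq_len(nrow(records))) {
    ac <- records$all_cause[i]
    if (ac == 0 || sum(cnt[i, ]) == 0) next
    path <- multiplicity_path[[records$arm[i]]]
    m <- interp_multiplicity(path, records$month_index[i], n_m)
    target <- as.integer(round_half_away(ac * m))
    cnt[i, ] <- apportion_largest_remainder(cnt[i, ], target)
  }
  records[, categories] <- cnt
  records
}

#' @rdname write_records
#' @export
record_categories <- function(records) {
  nm <- names(records)
  core <- c("cluster_id", "pair_id", "arm", "confounder_score", "year",
            "month", "month_index", "period", "all_cause")
  setdiff(nm, core)
}

#' Read and write facility-record CSV files
#'
#' Flat CSV schema: `cluster_id, pair_id, arm, confounder_score, year, month,
#' month_index, period, <one column per category>, all_cause`.
#'
#' @param records data.frame of cluster-month records.
#' @param path file path.
#' @return `read_records` returns the records data.frame with `period`
#'   restored as a factor; `write_records` returns `path` invisibly;
#'   `record_categories` returns the category column names.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  lev <- c("baseline", setdiff(unique(rec$period), "baseline"))
  rec$period <- factor(rec$period, levels = lev)
  rec
}
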