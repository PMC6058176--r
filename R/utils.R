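#' Round half away from zero
#'
#' Base [round()] rounds half to even; published tables in this field
#' conventionally round half away from zero, so display rounding goes through
#' this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  # signif() guards against binary-representation dust just below a .5
  sign(x) * floor(signif(abs(x) * p, 12) + 0.5) / p
}

#' Largest-remainder integer apportionment
#'
#' Distributes an integer `total` across categories proportionally to
#' non-negative `weights` (Hamilton apportionment): each category gets the
#' floor of its exact quota, and the remaining units go to the categories with
#' the largest fractional remainders. Ties are broken by category order.
#'
#' @param weights non-negative numeric vector of proportionality weights.
#' @param total non-negative integer to distribute.
#' @return integer vector summing exactly to `total` (all zeros if
#'   `sum(weights) == 0`).
#' @examples
#' apportion_largest_remainder(c(60, 40, 100), 100)  # 30 20 50
#' apportion_largest_remainder(c(1, 1, 1), 100)      # 34 33 33
#' @export
apportion_largest_remainder <- function(weights, total) {
  if (any(weights < 0)) stop("weights must be non-negative")
  if (length(total) != 1L || is.na(total) || total < 0) {
    stop("total must be a single non-negative integer")
  }
  total <- as.integer(round(total))
  k <- length(weights)
  if (sum(weights) == 0) return(integer(k))
  quota <- weights * total / sum(weights)
  base <- floor(quota)
  rem <- quota - base
  left <- total - sum(base)
  out <- as.integer(base)
  if (left > 0) {
    # stable order: larger remainder first, earlier category wins ties
    take <- order(-rem, seq_len(k))[seq_len(left)]
    out[take] <- out[take] + 1L
  }
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# md5-based deterministic child seeds: hash "<seed>/<tag>" and take 7 hex
# digits so the result stays below 2^31.
child_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(paste0(seed, "/", tag), f)
  h <- unname(tools::md5sum(f))
  strtoi(substr(h, 1, 7), base = 16L)
}

# Hash a configuration list for provenance blocks.
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
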