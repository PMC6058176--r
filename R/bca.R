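#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Pure-formula BCa construction from a replicate stream. The bias-correction
#' constant is `z0 = qnorm(#{theta* < theta_hat} / B)`; the acceleration `a`
#' comes from the jackknife values,
#' `a = sum((tbar - t_i)^3) / (6 * (sum((tbar - t_i)^2))^{3/2})`;
#' the interval endpoints are the bootstrap quantiles at the remapped levels
#' `alpha_k = pnorm(z0 + (z0 + z_k) / (1 - a * (z0 + z_k)))` for
#' `z_k = qnorm(alpha/2), qnorm(1 - alpha/2)`. Quantiles use the `(B + 1) *
#' alpha` order-statistic rule. With `z0 = 0` and `a = 0` the interval reduces
#' to the percentile interval on the same replicate stream.
#'
#' @param t0 point estimate on the original data.
#' @param t numeric vector of B bootstrap replicate estimates.
#' @param jack numeric vector of leave-one-unit-out jackknife estimates used
#'   for the acceleration constant; `NULL` sets `a = 0`.
#' @param level confidence level (two-sided).
#' @return list of class `bca_result`: `t0`, `B`, `z0`, `a`, `level`,
#'   `ci_low`, `ci_high`, and `degenerate` (all replicates identical, interval
#'   collapsed).
#' @export
bca_interval <- function(t0, t, jack = NULL, level = 0.95) {
  t <- t[is.finite(t)]
  B <- length(t)
  if (B < 2) stop("need at least 2 finite bootstrap replicates")
  alpha <- 1 - level
  if (length(unique(t)) == 1L) {
    warning("degenerate bootstrap distribution: interval collapses to a point")
    out <- list(t0 = t0, B = B, z0 = 0, a = 0, level = level,
                ci_low = t[1], ci_high = t[1], degenerate = TRUE)
    class(out) <- "bca_result"
    return(out)
  }
  prop <- sum(t < t0) / B
  # clamp away from 0/1 so z0 stays finite when the point estimate falls
  # outside the replicate range
  prop <- min(max(prop, 1 / (2 * B)), 1 - 1 / (2 * B))
  z0 <- stats::qnorm(prop)
  a <- if (is.null(jack) || length(jack) < 3) 0 else jackknife_accel(jack)
  zl <- stats::qnorm(alpha / 2)
  zu <- stats::qnorm(1 - alpha / 2)
  a1 <- stats::pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
  a2 <- stats::pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
  q <- boot_quantile(t, c(a1, a2))
  out <- list(t0 = t0, B = B, z0 = z0, a = a, level = level,
              ci_low = q[1], ci_high = q[2], degenerate = FALSE)
  class(out) <- "bca_result"
  out
}

# acceleration constant from jackknife values
jackknife_accel <- function(jack) {
  d <- mean(jack) - jack
  denom <- 6 * sum(d^2)^1.5
  if (denom == 0) return(0)
  sum(d^3) / denom
}

# (B + 1) * alpha order-statistic quantile with interpolation between
# adjacent order statistics on the normal-quantile scale (the standard BCa
# quantile rule), clamped to the observed replicates at the extremes
boot_quantile <- function(t, probs) {
  ts <- sort(t)
  B <- length(ts)
  vapply(probs, function(p) {
    k <- (B + 1) * p
    k1 <- floor(k)
    if (k1 < 1) return(ts[1])
    if (k1 >= B) return(ts[B])
    w <- (stats::qnorm(k / (B + 1)) - stats::qnorm(k1 / (B + 1))) /
      (stats::qnorm((k1 + 1) / (B + 1)) - stats::qnorm(k1 / (B + 1)))
    ts[k1] + w * (ts[k1 + 1] - ts[k1])
  }, numeric(1))
}

#' @export
print.bca_result <- function(x, ...) {
  cat(sprintf("BCa interval (level %.2f, B = %d): [%.6g, %.6g]\n",
              x$level, x$B, x$ci_low, x$ci_high))
  cat(sprintf("  t0 = %.6g, z0 = %.4f, a = %.4f%s\n", x$t0, x$z0, x$a,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Generic cluster bootstrap with BCa intervals
#'
#' Resamples sampling units (clusters) with replacement, stratified by arm so
#' each resample preserves the per-arm cluster counts, recomputes a statistic
#' on each resample, and builds BCa intervals per component using
#' leave-one-cluster-out jackknife acceleration. Replicate seeds derive
#' deterministically from `seed`, so runs are reproducible.
#'
#' @param records data.frame with `cluster_id` and `arm` columns.
#' @param statistic function of a records data.frame returning a named numeric
#'   vector.
#' @param B number of bootstrap replicates (>= 200 for interval construction).
#' @param level confidence level.
#' @param seed integer seed for the resampling stream.
#' @param strata column name used for stratified resampling (`"arm"`), or
#'   `NULL` for unstratified cluster resampling.
#' @param unit `"cluster"` resamples individual clusters within arm;
#'   `"pair"` resamples matched pairs (both arms of a pair move together).
#' @param max_fail maximum tolerated fraction of failed refits.
#' @return list of class `cluster_boot`: `t0`, matrix `t` (B x components),
#'   per-component `bca_result`s, jackknife matrix, and `n_failed`.
#' @export
cluster_bootstrap <- function(records, statistic, B = 1000, level = 0.95,
                              seed = NULL, strata = "arm",
                              unit = c("cluster", "pair"), max_fail = 0.05) {
  unit <- match.arg(unit)
  if (B < 200) warning("B < 200 is too small for stable BCa intervals")
  t0 <- statistic(records)
  nm <- names(t0)

  cl_tab <- unique(records[, c("cluster_id", "pair_id", "arm")])
  resample_ids <- function() {
    if (unit == "pair") {
      pairs <- unique(cl_tab$pair_id)
      take <- sample(pairs, length(pairs), replace = TRUE)
      unlist(lapply(take, function(p) cl_tab$cluster_id[cl_tab$pair_id == p]))
    } else if (is.null(strata)) {
      sample(cl_tab$cluster_id, nrow(cl_tab), replace = TRUE)
    } else {
      unlist(lapply(split(cl_tab$cluster_id, cl_tab[[strata]]),
                    function(ids) sample(ids, length(ids), replace = TRUE)))
    }
  }

  rows_by_cluster <- split(seq_len(nrow(records)), records$cluster_id)
  build <- function(ids) {
    idx <- unlist(rows_by_cluster[ids], use.names = FALSE)
    out <- records[idx, , drop = FALSE]
    # relabel duplicated clusters so random-effect grouping stays well defined
    reps <- unlist(lapply(seq_along(ids), function(k) {
      rep(k, length(rows_by_cluster[[ids[k]]]))
    }))
    out$cluster_id <- paste0(out$cluster_id, "_b", reps)
    out
  }

  t_mat <- matrix(NA_real_, nrow = B, ncol = length(t0),
                  dimnames = list(NULL, nm))
  n_failed <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      rb <- build(resample_ids())
      tb <- tryCatch(statistic(rb), error = function(e) NULL,
                     warning = function(w) tryCatch(
                       suppressWarnings(statistic(rb)),
                       error = function(e) NULL))
      if (is.null(tb) || any(!is.finite(tb))) {
        n_failed <- n_failed + 1L
      } else {
        t_mat[b, ] <- tb
      }
    }
  })
  if (n_failed / B > max_fail) {
    stop(sprintf("%d of %d bootstrap refits failed (> %.0f%% tolerated)",
                 n_failed, B, 100 * max_fail))
  }

  # leave-one-cluster-out jackknife for the acceleration constant
  cl_ids <- cl_tab$cluster_id
  jack <- matrix(NA_real_, nrow = length(cl_ids), ncol = length(t0),
                 dimnames = list(cl_ids, nm))
  for (j in seq_along(cl_ids)) {
    keep <- records$cluster_id != cl_ids[j]
    tj <- tryCatch(suppressWarnings(
      statistic(records[keep, , drop = FALSE])), error = function(e) NULL)
    if (!is.null(tj)) jack[j, ] <- tj
  }

  intervals <- lapply(nm, function(k) {
    tk <- t_mat[, k]
    bca_interval(t0[[k]], tk[is.finite(tk)],
                 jack = jack[is.finite(jack[, k]), k], level = level)
  })
  names(intervals) <- nm
  out <- list(t0 = t0, t = t_mat, intervals = intervals, jack = jack,
              B = B, level = level, n_failed = n_failed)
  class(out) <- "cluster_boot"
  out
}

# Fast plain-Poisson bootstrap for the ITS period effects: the design matrix
# is built once and resamples are row-indexed (a cluster's covariate rows do
# not change when it is resampled, and the glm path has no cluster term), with
# warm starts from the full-data linear predictor. Statistically identical to
# refitting via fit_its(method = "glm") on each resample.
its_glm_boot <- function(records, category, B = 1000, level = 0.95,
                         seed = NULL, unit = c("cluster", "pair"),
                         period_main = FALSE, max_fail = 0.05) {
  unit <- match.arg(unit)
  if (B < 200) warning("B < 200 is too small for stable BCa intervals")
  df <- its_frame(records, category, period_main = period_main)
  periods <- attr(df, "periods")
  X <- its_model_matrix(df, period_main = period_main)
  y <- df$y
  terms <- paste0("int_", periods)
  fit0 <- stats::glm.fit(X, y, family = stats::poisson())
  eta0 <- log(pmax(fit0$fitted.values, 1e-8))
  t0 <- stats::setNames(fit0$coefficients[terms], periods)

  refit <- function(idx) {
    f <- tryCatch(
      suppressWarnings(stats::glm.fit(X[idx, , drop = FALSE], y[idx],
                                      family = stats::poisson(),
                                      etastart = eta0[idx])),
      error = function(e) NULL)
    if (is.null(f) || !f$converged) return(rep(NA_real_, length(terms)))
    f$coefficients[terms]
  }

  cl_tab <- unique(records[, c("cluster_id", "pair_id", "arm")])
  rows_by_cluster <- split(seq_len(nrow(records)), records$cluster_id)
  resample_idx <- function() {
    ids <- if (unit == "pair") {
      pairs <- unique(cl_tab$pair_id)
      take <- sample(pairs, length(pairs), replace = TRUE)
      unlist(lapply(take, function(p) cl_tab$cluster_id[cl_tab$pair_id == p]))
    } else {
      unlist(lapply(split(cl_tab$cluster_id, cl_tab$arm),
                    function(x) sample(x, length(x), replace = TRUE)))
    }
    unlist(rows_by_cluster[ids], use.names = FALSE)
  }

  t_mat <- matrix(NA_real_, nrow = B, ncol = length(periods),
                  dimnames = list(NULL, periods))
  n_failed <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      tb <- refit(resample_idx())
      if (any(!is.finite(tb))) n_failed <- n_failed + 1L else t_mat[b, ] <- tb
    }
  })
  if (n_failed / B > max_fail) {
    stop(sprintf("%d of %d bootstrap refits failed (> %.0f%% tolerated)",
                 n_failed, B, 100 * max_fail))
  }

  cl_ids <- cl_tab$cluster_id
  jack <- matrix(NA_real_, nrow = length(cl_ids), ncol = length(periods),
                 dimnames = list(cl_ids, periods))
  for (j in seq_along(cl_ids)) {
    idx <- setdiff(seq_len(nrow(records)), rows_by_cluster[[cl_ids[j]]])
    jack[j, ] <- refit(idx)
  }

  intervals <- lapply(periods, function(k) {
    tk <- t_mat[, k]
    bca_interval(t0[[k]], tk[is.finite(tk)],
                 jack = jack[is.finite(jack[, k]), k], level = level)
  })
  names(intervals) <- periods
  out <- list(t0 = t0, t = t_mat, intervals = intervals, jack = jack,
              B = B, level = level, n_failed = n_failed)
  class(out) <- "cluster_boot"
  out
}

#' Invert a BCa interval family into a two-sided p-value
#'
#' The p-value for the null `theta = null_value` is the smallest two-sided
#' level `alpha` at which the `1 - alpha` BCa interval (built from the same
#' replicate stream and constants) excludes the null value, found by
#' bisection. Values are clamped to `[1/B, 1]`: the replicate stream cannot
#' resolve smaller tail probabilities.
#'
#' @param bca a [bca_interval()] result.
#' @param t the replicate stream the interval was built from.
#' @param null_value the null hypothesis value (log rate ratio 0, say).
#' @return two-sided p-value.
#' @export
bca_p_value <- function(bca, t, null_value = 0) {
  t <- t[is.finite(t)]
  B <- length(t)
  if (bca$degenerate) return(if (bca$t0 == null_value) 1 else 1 / B)
  covers <- function(alpha) {
    zl <- stats::qnorm(alpha / 2)
    zu <- stats::qnorm(1 - alpha / 2)
    a1 <- stats::pnorm(bca$z0 + (bca$z0 + zl) / (1 - bca$a * (bca$z0 + zl)))
    a2 <- stats::pnorm(bca$z0 + (bca$z0 + zu) / (1 - bca$a * (bca$z0 + zu)))
    q <- boot_quantile(t, c(a1, a2))
    q[1] <= null_value && null_value <= q[2]
  }
  lo <- 1 / B
  hi <- 1 - 1e-9
  if (covers(hi)) return(1)
  if (!covers(lo)) return(lo)
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (covers(mid)) lo <- mid else hi <- mid
  }
  hi
}

#' Period effects with BCa cluster-bootstrap confidence intervals
#'
#' Full inference path for one diagnosis category: fit the interrupted
#' time-series model, then bootstrap clusters (stratified by arm, preserving
#' the per-arm cluster counts) to obtain BCa confidence intervals and
#' inversion p-values for each campaign-period rate ratio. Wald p-values from
#' the model's information matrix are reported alongside; the bootstrap
#' inversion p-value is primary.
#'
#' @param records data.frame in the [simulate_trial()] schema.
#' @param category diagnosis-category column to analyse.
#' @param B number of bootstrap replicates.
#' @param level confidence level.
#' @param seed integer seed.
#' @param method fitting path passed to [fit_its()]; bootstrap refits use the
#'   same path.
#' @param nagq quadrature nodes for the mixed-model path.
#' @param unit resampling unit, `"cluster"` or `"pair"`.
#' @param period_main passed to [fit_its()].
#' @return data.frame of class `period_effects_ci`: one row per campaign
#'   period with `rate_ratio`, `ci_low`, `ci_high`, `pct_change` (+ CI),
#'   bootstrap inversion `p_value` and `p_wald`; the `cluster_boot` object is
#'   attached as attribute `"boot"`.
#' @export
its_boot <- function(records, category, B = 1000, level = 0.95, seed = NULL,
                     method = c("glmer", "glm"), nagq = 9,
                     unit = c("cluster", "pair"), period_main = FALSE) {
  method <- match.arg(method)
  unit <- match.arg(unit)
  if (method == "glm") {
    bt <- its_glm_boot(records, category, B = B, level = level, seed = seed,
                       unit = unit, period_main = period_main)
  } else {
    stat <- function(rec) {
      f <- fit_its(rec, category, method = method, nagq = nagq,
                   period_main = period_main)
      pe <- period_effects(f)
      stats::setNames(pe$log_rr, pe$period)
    }
    bt <- cluster_bootstrap(records, stat, B = B, level = level, seed = seed,
                            unit = unit)
  }
  fit <- fit_its(records, category, method = method, nagq = nagq,
                 period_main = period_main)
  pe <- period_effects(fit)
  rows <- lapply(seq_len(nrow(pe)), function(i) {
    p <- pe$period[i]
    iv <- bt$intervals[[p]]
    tk <- bt$t[, p]
    data.frame(category = category, period = p,
               rate_ratio = pe$rate_ratio[i],
               ci_low = exp(iv$ci_low), ci_high = exp(iv$ci_high),
               pct_change = pe$pct_change[i],
               pct_low = round_half_away(100 * (exp(iv$ci_low) - 1)),
               pct_high = round_half_away(100 * (exp(iv$ci_high) - 1)),
               p_value = bca_p_value(iv, tk[is.finite(tk)], 0),
               p_wald = 2 * stats::pnorm(-abs(pe$log_rr[i] / pe$se[i])),
               z0 = iv$z0, accel = iv$a, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "boot") <- bt
  attr(out, "fit") <- fit
  class(out) <- c("period_effects_ci", "data.frame")
  out
}

#' @export
print.period_effects_ci <- function(x, ...) {
  cat(sprintf("Period effects for '%s' with BCa cluster-bootstrap CIs (B = %d)\n",
              x$category[1], attr(x, "boot")$B))
  df <- as.data.frame(x)
  df$display <- sprintf("%+d%% (%d%% to %d%%; p=%.3f)", df$pct_change,
                        df$pct_low, df$pct_high, df$p_value)
  print(df[, c("period", "rate_ratio", "ci_low", "ci_high", "display")],
        row.names = FALSE)
  invisible(x)
}
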