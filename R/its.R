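#' Interrupted time-series model for one diagnosis category
#'
#' Fits the campaign-effect model to monthly cluster-level counts of one
#' diagnosis category: a log-link Poisson regression with a linear secular
#' trend in `month_index`, month-of-year indicators for seasonality, an
#' intervention-arm indicator for systematic baseline differences, the cluster
#' confounder score, and period-by-arm interaction indicators for each
#' campaign year (the baseline period carries none). The cluster enters as a
#' normal random intercept, integrated by adaptive Gauss-Hermite quadrature
#' (falling back to the Laplace approximation if quadrature fails). With
#' `method = "glm"` the random intercept is dropped and a plain Poisson
#' regression is fitted — exact when between-cluster heterogeneity is absent,
#' and the fast path used inside bootstrap refits.
#'
#' No exposure offset is used: the model describes raw monthly counts, as
#' routine systems provide no reliable denominators.
#'
#' @param records data.frame in the [simulate_trial()] schema.
#' @param category name of the count column to model.
#' @param method `"glmer"` (mixed model) or `"glm"` (no random intercept).
#' @param nagq number of adaptive Gauss-Hermite quadrature nodes (>= 1;
#'   1 is the Laplace approximation).
#' @param period_main also include period main effects (control-arm level
#'   shifts per campaign year). Off by default: the secular trend and
#'   seasonality carry the control-arm time course.
#' @return object of class `its_fit`: coefficients on the log scale,
#'   random-intercept variance (`re_var`), log-likelihood, convergence flag,
#'   the period labels, and the model frame specification.
#' @seealso [period_effects()], [its_boot()]
#' @export
fit_its <- function(records, category, method = c("glmer", "glm"),
                    nagq = 9, period_main = FALSE) {
  method <- match.arg(method)
  df <- its_frame(records, category, period_main = period_main)
  periods <- attr(df, "periods")

  # separation guard: a campaign period with all-zero counts in one arm
  # cannot identify its interaction coefficient
  for (p in periods) {
    sel <- df$period == p
    for (a in 0:1) {
      if (any(sel & df$arm_i == a) && sum(df$y[sel & df$arm_i == a]) == 0) {
        warning(sprintf("separation: zero '%s' counts in %s arm during %s",
                        category, c("control", "intervention")[a + 1], p))
      }
    }
  }

  if (method == "glm") {
    X <- its_model_matrix(df, period_main = period_main)
    fit <- stats::glm.fit(X, df$y, family = stats::poisson())
    res <- list(coefficients = fit$coefficients, re_var = 0,
                logLik = poisson_loglik(df$y, fit$fitted.values),
                converged = fit$converged, method = "glm",
                vcov = glm_vcov(X, fit),
                category = category, periods = periods,
                period_main = period_main, n_clusters =
                  length(unique(df$cluster_id)), nobs = nrow(df))
  } else {
    form <- its_formula(period_main)
    ctrl <- lme4::glmerControl(check.conv.singular = "ignore",
                               calc.derivs = FALSE)
    m <- tryCatch(
      suppressMessages(lme4::glmer(form, data = df, family = stats::poisson(),
                                   nAGQ = nagq, control = ctrl)),
      error = function(e) NULL)
    if (is.null(m) && nagq > 1) {
      m <- tryCatch(
        suppressMessages(lme4::glmer(form, data = df,
                                     family = stats::poisson(), nAGQ = 1,
                                     control = ctrl)),
        error = function(e) NULL)
    }
    if (is.null(m)) stop("mixed-model fit failed for category ", category)
    conv <- length(m@optinfo$conv$lme4$messages) == 0
    if (!conv) warning("mixed-model fit did not converge cleanly for ",
                       category)
    res <- list(coefficients = lme4::fixef(m),
                re_var = unname(lme4::VarCorr(m)$cluster_id[1, 1]),
                logLik = as.numeric(stats::logLik(m)),
                converged = conv, method = "glmer",
                vcov = as.matrix(stats::vcov(m)),
                category = category, periods = periods,
                period_main = period_main,
                n_clusters = length(unique(df$cluster_id)), nobs = nrow(df))
  }
  class(res) <- "its_fit"
  res
}

# model frame shared by both fitting paths
its_frame <- function(records, category, period_main = FALSE) {
  if (!category %in% names(records)) stop("unknown category: ", category)
  arms <- sort(unique(records$arm))
  if (!all(c("control", "intervention") %in% arms)) {
    stop("records must contain both arms")
  }
  per_arm <- tapply(records$cluster_id, records$arm,
                    function(x) length(unique(x)))
  if (any(per_arm < 2)) stop("need at least 2 clusters per arm")
  periods <- setdiff(levels(factor(records$period)), "baseline")
  df <- data.frame(y = records[[category]],
                   month_index = records$month_index,
                   moy = factor(records$month, levels = 1:12),
                   arm_i = as.integer(records$arm == "intervention"),
                   confounder_score = records$confounder_score,
                   period = factor(as.character(records$period),
                                   levels = c("baseline", periods)),
                   cluster_id = factor(records$cluster_id))
  if (all(df$y == 0)) stop("all-zero response for category ", category)
  for (p in periods) {
    df[[paste0("int_", p)]] <- df$arm_i * as.integer(df$period == p)
  }
  attr(df, "periods") <- periods
  df
}

its_formula <- function(period_main = FALSE, periods = c("year1", "year2",
                                                         "year3")) {
  rhs <- c("month_index", "moy", "arm_i", "confounder_score",
           if (period_main) "period",
           paste0("int_", periods))
  stats::as.formula(paste("y ~", paste(rhs, collapse = " + "),
                          "+ (1 | cluster_id)"))
}

its_model_matrix <- function(df, period_main = FALSE) {
  periods <- attr(df, "periods")
  rhs <- c("month_index", "moy", "arm_i", "confounder_score",
           if (period_main) "period",
           paste0("int_", periods))
  stats::model.matrix(stats::as.formula(paste("~", paste(rhs, collapse = " + "))),
                      df)
}

poisson_loglik <- function(y, mu) sum(stats::dpois(y, mu, log = TRUE))

glm_vcov <- function(X, fit) {
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  v <- tryCatch(solve(XtWX), error = function(e) matrix(NA, ncol(X), ncol(X)))
  dimnames(v) <- list(colnames(X), colnames(X))
  v
}

#' @export
print.its_fit <- function(x, ...) {
  cat(sprintf("Interrupted time-series Poisson fit ('%s', %s)\n",
              x$category, x$method))
  cat(sprintf("  %d observations, %d clusters; random-intercept SD %.4f\n",
              x$nobs, x$n_clusters, sqrt(x$re_var)))
  cat(sprintf("  log-likelihood %.2f; converged: %s\n",
              x$logLik, x$converged))
  pe <- period_effects(x)
  cat("Period effects (intervention vs control):\n")
  print(pe, row.names = FALSE)
  invisible(x)
}

#' @export
coef.its_fit <- function(object, ...) object$coefficients

#' @export
summary.its_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- data.frame(estimate = object$coefficients, se = se,
                    z = object$coefficients / se)
  tab$p_wald <- 2 * stats::pnorm(-abs(tab$z))
  out <- list(category = object$category, method = object$method,
              coefficients = tab, re_var = object$re_var,
              logLik = object$logLik, converged = object$converged,
              period_effects = period_effects(object))
  class(out) <- "summary.its_fit"
  out
}

#' @export
print.summary.its_fit <- function(x, ...) {
  cat(sprintf("ITS Poisson fit for '%s' (%s)\n", x$category, x$method))
  print(round(x$coefficients, 4))
  cat(sprintf("random-intercept variance %.5f; logLik %.2f\n",
              x$re_var, x$logLik))
  print(x$period_effects, row.names = FALSE)
  invisible(x)
}

#' @export
confint.its_fit <- function(object, parm, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * se, object$coefficients + z * se)
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                             1 - (1 - level) / 2))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Period-specific intervention rate ratios from a fitted ITS model
#'
#' Exponentiates each period-by-arm interaction coefficient into a rate ratio
#' and expresses it as a percentage change in consultations,
#' `100 * (RR - 1)`, rounded half away from zero to the nearest integer for
#' display.
#'
#' @param fit an [fit_its()] object.
#' @return data.frame with columns `category`, `period`, `log_rr`,
#'   `rate_ratio`, `pct_change` and the Wald standard error `se`.
#' @export
period_effects <- function(fit) {
  stopifnot(inherits(fit, "its_fit"))
  terms <- paste0("int_", fit$periods)
  if (!all(terms %in% names(fit$coefficients))) {
    stop("fit is missing period interaction terms")
  }
  b <- fit$coefficients[terms]
  se <- sqrt(diag(fit$vcov))[terms]
  data.frame(category = fit$category, period = fit$periods,
             log_rr = unname(b), rate_ratio = unname(exp(b)),
             pct_change = unname(round_half_away(100 * (exp(b) - 1))),
             se = unname(se), row.names = NULL)
}
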