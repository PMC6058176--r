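#' Under-five mortality envelope
#'
#' Converts per-year under-five mortality rates and live births into the total
#' and cause-specific deaths expected in the absence of the intervention —
#' the denominator for percentage mortality reductions. Cause fractions may
#' sum to less than 1; the remainder is deaths from non-targeted causes.
#'
#' @param years integer vector of calendar years.
#' @param u5mr deaths per 1000 live births, one per year.
#' @param live_births live births per year (recycled if scalar).
#' @param cause_fractions named numeric vector mapping cause to its fraction
#'   of under-five deaths.
#' @return object of class `mortality_envelope`: `years`, `deaths` (per
#'   year), and matrix `cause_deaths` (cause x year).
#' @examples
#' mortality_envelope(2012, 137, 1e5, c(malaria = 0.25))
#' @export
mortality_envelope <- function(years, u5mr, live_births, cause_fractions) {
  if (any(u5mr <= 0)) stop("u5mr must be positive")
  if (any(live_births <= 0)) stop("live births must be positive")
  if (any(cause_fractions < 0) || any(cause_fractions > 1) ||
      sum(cause_fractions) > 1 + 1e-9) {
    stop("cause fractions must lie in [0, 1] and sum to at most 1")
  }
  u5mr <- rep_len(u5mr, length(years))
  live_births <- rep_len(live_births, length(years))
  deaths <- u5mr * live_births / 1000
  cause_deaths <- outer(cause_fractions, deaths)
  dimnames(cause_deaths) <- list(names(cause_fractions), as.character(years))
  structure(list(years = years, u5mr = u5mr, live_births = live_births,
                 deaths = stats::setNames(deaths, as.character(years)),
                 cause_fractions = cause_fractions,
                 cause_deaths = cause_deaths),
            class = "mortality_envelope")
}

#' @export
print.mortality_envelope <- function(x, ...) {
  cat("Under-five mortality envelope\n")
  print(data.frame(year = x$years, u5mr = x$u5mr,
                   live_births = x$live_births,
                   deaths = round(x$deaths)), row.names = FALSE)
  invisible(x)
}

#' Intervention specification
#'
#' Describes one modelled intervention: its effectiveness (proportional
#' mortality reduction among covered, affected cases), the affected fraction
#' per linked cause of death, and how facility-utilisation effects map to
#' treatment coverage. Coverage modes: `"treatment_with_receipt"` scales the
#' utilisation increase by the proportion of attenders who actually receive
#' the effective treatment; `"careseeking_proxy"` treats care-seeking itself
#' as the coverage proxy (the convention for oral antibiotics for pneumonia);
#' `"direct"` applies the utilisation increase directly (antenatal care,
#' facility delivery).
#'
#' @param name intervention label.
#' @param effectiveness E in `[0, 1]`.
#' @param causes character vector of linked causes of death.
#' @param affected_fraction AF in `[0, 1]`, recycled across causes.
#' @param coverage_mode one of `"treatment_with_receipt"`,
#'   `"careseeking_proxy"`, `"direct"`.
#' @param receipt proportion q of attenders receiving effective treatment
#'   (used by `"treatment_with_receipt"`).
#' @return object of class `intervention_spec`.
#' @export
intervention_spec <- function(name, effectiveness, causes,
                              affected_fraction = 1,
                              coverage_mode = c("treatment_with_receipt",
                                                "careseeking_proxy",
                                                "direct"),
                              receipt = 1) {
  coverage_mode <- match.arg(coverage_mode)
  stopifnot(effectiveness >= 0, effectiveness <= 1,
            all(affected_fraction >= 0), all(affected_fraction <= 1),
            receipt >= 0, receipt <= 1)
  af <- rep_len(affected_fraction, length(causes))
  names(af) <- causes
  structure(list(name = name, effectiveness = effectiveness,
                 causes = causes, affected_fraction = af,
                 coverage_mode = coverage_mode, receipt = receipt),
            class = "intervention_spec")
}

#' Map a utilisation effect to a treatment-coverage level
#'
#' Applies a relative increase in facility attendances to a baseline coverage
#' level. Under `"treatment_with_receipt"` the attendance increase is first
#' scaled by the receipt proportion q (attenders actually treated):
#' `C_y = C0 * (1 + r * q)`. Under `"careseeking_proxy"` and `"direct"`,
#' `C_y = C0 * (1 + r)`. Results are capped at 1 with a warning (scenario
#' saturation).
#'
#' @param c0 baseline coverage in `[0, 1]`.
#' @param r relative utilisation increase (e.g. 0.56 for +56%); must exceed
#'   -1.
#' @param q receipt proportion in `[0, 1]`.
#' @param mode coverage mode (see [intervention_spec()]).
#' @return coverage in `[0, 1]`, vectorised over `r`.
#' @export
coverage_from_utilisation <- function(c0, r, q = 1,
                                      mode = c("treatment_with_receipt",
                                               "careseeking_proxy",
                                               "direct")) {
  mode <- match.arg(mode)
  stopifnot(c0 >= 0, c0 <= 1, q >= 0, q <= 1)
  if (any(r <= -1)) stop("utilisation effects must exceed -1")
  mult <- if (mode == "treatment_with_receipt") 1 + r * q else 1 + r
  cy <- c0 * mult
  if (any(cy > 1)) {
    warning("coverage capped at 1 (scenario saturation)")
    cy <- pmin(cy, 1)
  }
  cy
}

#' Impact fraction of a coverage change
#'
#' Fraction of current cause-specific deaths averted when coverage moves from
#' `c0` to `c1` for an intervention with effectiveness `e` and affected
#' fraction `af`:
#' `phi = e * af * (c1 - c0) / (1 - e * af * c0)`.
#' The denominator rescales to the deaths still occurring at baseline
#' coverage; equivalently `phi = 1 - (1 - e*af*c1) / (1 - e*af*c0)`.
#'
#' @param e effectiveness in `[0, 1]`.
#' @param af affected fraction in `[0, 1]`.
#' @param c0,c1 baseline and achieved coverage in `[0, 1]`.
#' @return impact fraction (negative when `c1 < c0`). Vectorised.
#' @examples
#' impact_fraction(0.87, 1, 0.3, 0.4)
#' @export
impact_fraction <- function(e, af, c0, c1) {
  k <- e * af
  if (any(c(c0, c1) < 0) || any(c(c0, c1) > 1)) {
    stop("coverages must lie in [0, 1]")
  }
  denom <- 1 - k * c0
  if (any(denom <= 0)) stop("e * af * c0 must be < 1")
  k * (c1 - c0) / denom
}

#' Combine impact fractions acting on one cause
#'
#' Residual multiplication: independent interventions each remove their
#' impact fraction from the deaths the previous ones left, so
#' `phi_comb = 1 - prod(1 - phi_i)`. Permutation-invariant; a fraction of 1
#' (every death from the cause averted) saturates the combination.
#'
#' @param phi numeric vector of impact fractions, each <= 1.
#' @return combined impact fraction.
#' @export
combine_impact_fractions <- function(phi) {
  if (any(phi > 1)) stop("impact fractions must be <= 1")
  1 - prod(1 - phi)
}

#' Deaths averted by a set of coverage changes
#'
#' The deaths-averted engine: for each year and cause, impact fractions of
#' all interventions linked to that cause are combined by residual
#' multiplication and applied to the cause-specific mortality envelope. Only
#' the modelled interventions contribute, so lives saved by any other
#' programme are excluded by construction. Within a cause, averted deaths are
#' attributed to interventions proportionally to their individual impact
#' fractions.
#'
#' @param envelope a [mortality_envelope()].
#' @param specs list of [intervention_spec()] objects.
#' @param coverage data.frame with columns `intervention`, `year`, `c0`,
#'   `c1` — one row per intervention-year.
#' @return object of class `lives_saved`: `by_year` (deaths, averted,
#'   `pct_reduction`), `by_cell` (year x intervention x cause attribution),
#'   and `average_reduction` (deaths-weighted, across years).
#' @export
lives_saved <- function(envelope, specs, coverage) {
  stopifnot(inherits(envelope, "mortality_envelope"))
  names(specs) <- vapply(specs, `[[`, "", "name")
  missing_specs <- setdiff(unique(coverage$intervention), names(specs))
  if (length(missing_specs)) {
    stop("no specification for intervention(s): ",
         paste(missing_specs, collapse = ", "))
  }
  bad_causes <- setdiff(unlist(lapply(specs, `[[`, "causes")),
                        names(envelope$cause_fractions))
  if (length(bad_causes)) {
    stop("intervention linked to cause(s) missing from the envelope: ",
         paste(bad_causes, collapse = ", "))
  }
  years <- envelope$years
  if (!all(coverage$year %in% years)) stop("coverage years outside envelope")

  cells <- list()
  by_year <- data.frame(year = years,
                        deaths = as.numeric(envelope$deaths),
                        averted = 0)
  for (yi in seq_along(years)) {
    y <- years[yi]
    cov_y <- coverage[coverage$year == y, , drop = FALSE]
    for (cause in names(envelope$cause_fractions)) {
      phis <- numeric(0)
      who <- character(0)
      for (i in seq_len(nrow(cov_y))) {
        sp <- specs[[cov_y$intervention[i]]]
        if (!cause %in% sp$causes) next
        phis <- c(phis, impact_fraction(sp$effectiveness,
                                        sp$affected_fraction[[cause]],
                                        cov_y$c0[i], cov_y$c1[i]))
        who <- c(who, sp$name)
      }
      if (!length(phis)) next
      phi_comb <- combine_impact_fractions(phis)
      averted_cause <- envelope$cause_deaths[cause, yi] * phi_comb
      share <- if (sum(abs(phis)) > 0) phis / sum(phis) else
        rep(1 / length(phis), length(phis))
      cells[[length(cells) + 1L]] <-
        data.frame(year = y, intervention = who, cause = cause,
                   phi = phis, averted = averted_cause * share)
      by_year$averted[yi] <- by_year$averted[yi] + averted_cause
    }
  }
  by_year$pct_reduction <- 100 * by_year$averted / by_year$deaths
  out <- list(by_year = by_year,
              by_cell = if (length(cells)) do.call(rbind, cells) else
                data.frame(year = integer(), intervention = character(),
                           cause = character(), phi = numeric(),
                           averted = numeric()),
              average_reduction = weighted_average_reduction(
                by_year$averted, by_year$deaths))
  class(out) <- "lives_saved"
  out
}

#' @export
print.lives_saved <- function(x, ...) {
  cat("Lives saved\n")
  df <- x$by_year
  df$averted <- round_half_away(df$averted)
  df$pct_reduction <- round_half_away(df$pct_reduction, 1)
  print(df, row.names = FALSE)
  cat(sprintf("total %d averted; deaths-weighted average reduction %.1f%%\n",
              round_half_away(sum(x$by_year$averted)), x$average_reduction))
  invisible(x)
}

#' Deaths-weighted average percentage mortality reduction
#'
#' Across-year summary: total averted deaths divided by total envelope
#' deaths, `100 * sum(averted) / sum(deaths)`, rounded to one decimal (half
#' away from zero) as in published summaries. When per-year percentage
#' reductions are supplied instead of deaths, the implied envelope
#' `deaths = 100 * averted / pct` is reconstructed first.
#'
#' @param averted lives saved per year.
#' @param deaths envelope deaths per year.
#' @param pct per-year percentage reductions, used when `deaths` is `NULL`.
#' @return percentage, rounded to 1 decimal.
#' @examples
#' weighted_average_reduction(c(1491, 817, 658), pct = c(9.7, 5.7, 5.5))
#' @export
weighted_average_reduction <- function(averted, deaths = NULL, pct = NULL) {
  if (is.null(deaths)) {
    if (is.null(pct)) stop("supply deaths or pct")
    deaths <- 100 * averted / pct
  }
  if (sum(deaths) <= 0) stop("zero total deaths")
  round_half_away(100 * sum(averted) / sum(deaths), 1)
}
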