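#' Penetration-index adjustment
#'
#' Scales lives saved in proportion to media exposure: effects measured in a
#' population where a fraction `p_ref` was exposed (e.g. 52% female radio
#' listenership in the trial zones) are rescaled by `p_target / p_ref` for a
#' population with exposure `p_target` (e.g. 45.2% nationally, a 13.1%
#' reduction). Scale-up to a higher-penetration medium (`p_target > p_ref`)
#' is allowed and noted.
#'
#' @param lives numeric lives saved (any shape).
#' @param p_target exposure proportion in the scenario population.
#' @param p_ref exposure proportion under which effects were measured (> 0).
#' @return rescaled lives, with attributes `factor` and `pct_reduction`
#'   (the implied percentage reduction, rounded to 1 decimal).
#' @examples
#' apply_penetration(1000, 0.452, 0.52)
#' @export
apply_penetration <- function(lives, p_target, p_ref) {
  if (p_ref <= 0) stop("p_ref must be positive")
  if (p_target > p_ref) {
    message("penetration target exceeds reference: scaling effects up")
  }
  f <- p_target / p_ref
  out <- lives * f
  attr(out, "factor") <- f
  attr(out, "pct_reduction") <- round_half_away(100 * (1 - f), 1)
  out
}

#' Discount lives saved
#'
#' Applies a fixed proportional reduction `d` to lives saved, representing a
#' weakened campaign format (e.g. spots-only delivery without long-format
#' programmes). Display rounding, where wanted, is half away from zero via
#' [round_half_away()].
#'
#' @param lives numeric lives saved.
#' @param d discount in `[0, 1)`.
#' @return `lives * (1 - d)`.
#' @export
apply_discount <- function(lives, d) {
  if (d < 0 || d >= 1) stop("discount must lie in [0, 1)")
  lives * (1 - d)
}

#' Discount grid from per-year lives saved and percentage reductions
#'
#' Scenario-table algebra: for each discount level, per-year lives saved are
#' multiplied by `1 - d` and rounded to the nearest integer (half away from
#' zero); percentage reductions scale by the same factor (the envelope is
#' unchanged) and are rounded to 1 decimal. Row totals are sums of the
#' rounded per-year cells, matching how published tables are assembled.
#'
#' @param lives per-year lives saved (undiscounted, unrounded or printed).
#' @param pct per-year percentage mortality reductions (optional).
#' @param discounts discount levels.
#' @return data.frame with one row per discount: per-year `lives_*` cells,
#'   `total`, and per-year `pct_*` cells when `pct` is given.
#' @examples
#' discount_grid(c(6690, 4143, 4055), pct = c(9.2, 5.6, 5.5))
#' @export
discount_grid <- function(lives, pct = NULL, discounts = c(0, 0.1, 0.2)) {
  yrs <- names(lives) %||% paste0("y", seq_along(lives))
  rows <- lapply(discounts, function(d) {
    cells <- round_half_away(apply_discount(lives, d))
    row <- as.data.frame(as.list(stats::setNames(cells,
                                                 paste0("lives_", yrs))))
    row$total <- sum(cells)
    if (!is.null(pct)) {
      p <- round_half_away(pct * (1 - d), 1)
      row <- cbind(row, as.data.frame(as.list(stats::setNames(
        p, paste0("pct_", yrs)))))
    }
    cbind(data.frame(discount = d), row)
  })
  do.call(rbind, rows)
}

#' Read a scenario configuration file
#'
#' Scenario files are YAML with the envelope (years, under-five mortality
#' rates per 1000 live births, live births, cause fractions), the intervention
#' specifications (effectiveness, affected fraction, linked causes, coverage
#' mode, receipt proportion, baseline coverage), the per-year utilisation
#' effects with confidence bounds, and optional penetration, population-scale
#' and discount settings.
#'
#' @param path YAML file path.
#' @return scenario configuration list.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (field in c("name", "envelope", "interventions")) {
    if (is.null(cfg[[field]])) stop("scenario file missing field: ", field)
  }
  cfg
}

scenario_envelope <- function(cfg, population_scale = 1) {
  env <- cfg$envelope
  mortality_envelope(years = as.integer(env$years),
                     u5mr = as.numeric(env$u5mr),
                     live_births = as.numeric(env$live_births) *
                       population_scale,
                     cause_fractions = unlist(env$cause_fractions))
}

scenario_specs <- function(cfg) {
  lapply(cfg$interventions, function(iv) {
    intervention_spec(name = iv$name,
                      effectiveness = iv$effectiveness,
                      causes = unlist(iv$causes),
                      affected_fraction = iv$affected_fraction %||% 1,
                      coverage_mode = iv$coverage_mode,
                      receipt = iv$receipt %||% 1)
  })
}

# coverage data.frame for one bound ("point", "low", "high")
scenario_coverage <- function(cfg, bound = "point",
                              rural_adjustment = 1) {
  years <- as.integer(cfg$envelope$years)
  rows <- lapply(cfg$interventions, function(iv) {
    eff <- iv$effects
    if (length(eff) != length(years)) {
      stop("intervention '", iv$name, "' needs one effect per envelope year")
    }
    r <- vapply(eff, function(e) {
      v <- e[[bound]]
      if (is.null(v)) stop("missing '", bound, "' bound for ", iv$name)
      as.numeric(v)
    }, numeric(1))
    c0 <- iv$baseline_coverage * rural_adjustment
    c1 <- vapply(r, function(ri) {
      suppressWarnings(coverage_from_utilisation(c0, ri, iv$receipt %||% 1,
                                                 iv$coverage_mode))
    }, numeric(1))
    data.frame(intervention = iv$name, year = years, c0 = c0, c1 = c1,
               r = r)
  })
  do.call(rbind, rows)
}

#' Project a scenario
#'
#' Runs the deaths-averted engine for a scenario configuration at the point
#' estimates and at the lower and upper confidence bounds of every
#' utilisation effect (the sensitivity analysis), then applies the
#' penetration index, optional population scaling and the discount grid.
#'
#' @param cfg scenario configuration list (see [read_scenario()]) or a YAML
#'   path.
#' @param discounts discount levels for the grid.
#' @param rural_adjustment multiplier applied to baseline coverages to map
#'   national survey values to the scenario population (default 1).
#' @return object of class `scenario_result`: `by_year` (point/low/high lives
#'   saved and percentage reductions), `totals`, `average_reduction`,
#'   `discount_table`, `penetration` and `coverage` detail.
#' @export
project_scenario <- function(cfg, discounts = c(0, 0.1, 0.2),
                             rural_adjustment = 1) {
  if (is.character(cfg)) cfg <- read_scenario(cfg)
  pop_mode <- cfg$population_scale_mode %||% "births"
  pop_scale <- cfg$population_scale %||% 1
  env <- scenario_envelope(cfg, if (pop_mode == "births") pop_scale else 1)
  specs <- scenario_specs(cfg)

  run_bound <- function(bound) {
    cov <- scenario_coverage(cfg, bound, rural_adjustment)
    ls <- lives_saved(env, specs, cov[, c("intervention", "year", "c0", "c1")])
    av <- ls$by_year$averted
    if (pop_mode == "posthoc") av <- av * pop_scale
    if (!is.null(cfg$penetration)) {
      av <- as.numeric(apply_penetration(av, cfg$penetration$target,
                                         cfg$penetration$reference))
    }
    list(averted = av, deaths = ls$by_year$deaths, detail = ls)
  }

  pt <- run_bound("point")
  has_bounds <- all(vapply(cfg$interventions, function(iv) {
    all(vapply(iv$effects, function(e) {
      !is.null(e$low) && !is.null(e$high)
    }, logical(1)))
  }, logical(1)))
  lo <- if (has_bounds) run_bound("low") else NULL
  hi <- if (has_bounds) run_bound("high") else NULL

  deaths <- pt$deaths
  by_year <- data.frame(year = env$years, deaths = deaths,
                        averted = pt$averted,
                        pct_reduction = 100 * pt$averted / deaths)
  if (has_bounds) {
    by_year$averted_low <- lo$averted
    by_year$averted_high <- hi$averted
    by_year$pct_low <- 100 * lo$averted / deaths
    by_year$pct_high <- 100 * hi$averted / deaths
  }
  pen <- if (!is.null(cfg$penetration)) {
    list(reference = cfg$penetration$reference,
         target = cfg$penetration$target,
         factor = cfg$penetration$target / cfg$penetration$reference,
         pct_reduction = round_half_away(
           100 * (1 - cfg$penetration$target / cfg$penetration$reference), 1))
  }
  out <- list(name = cfg$name, by_year = by_year,
              totals = c(point = sum(pt$averted),
                         low = if (has_bounds) sum(lo$averted) else NA,
                         high = if (has_bounds) sum(hi$averted) else NA),
              average_reduction = weighted_average_reduction(pt$averted,
                                                             deaths),
              discount_table = discount_grid(
                stats::setNames(pt$averted, env$years),
                pct = 100 * pt$averted / deaths, discounts = discounts),
              penetration = pen,
              coverage = scenario_coverage(cfg, "point", rural_adjustment),
              detail = pt$detail)
  class(out) <- "scenario_result"
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario '%s'\n", x$name))
  df <- x$by_year
  num <- setdiff(names(df), "year")
  df[num] <- lapply(df[num], function(v) round_half_away(v, 1))
  df$averted <- round_half_away(x$by_year$averted)
  if ("averted_low" %in% names(df)) {
    df$averted_low <- round_half_away(x$by_year$averted_low)
    df$averted_high <- round_half_away(x$by_year$averted_high)
  }
  print(df, row.names = FALSE)
  cat(sprintf("total lives saved %d", round_half_away(x$totals[["point"]])))
  if (!is.na(x$totals[["low"]])) {
    cat(sprintf(" (%d to %d)", round_half_away(x$totals[["low"]]),
                round_half_away(x$totals[["high"]])))
  }
  cat(sprintf("; average reduction %.1f%%\n", x$average_reduction))
  if (!is.null(x$penetration)) {
    cat(sprintf("penetration %0.1f%% -> %0.1f%% (%.1f%% reduction applied)\n",
                100 * x$penetration$reference, 100 * x$penetration$target,
                x$penetration$pct_reduction))
  }
  invisible(x)
}

#' Multi-country scale-up projection
#'
#' Applies the trial's utilisation effects to each country's own mortality
#' envelope, baseline coverages and media penetration, and tabulates lives
#' saved and percentage mortality reductions per year under each discount
#' level — the shape of a multi-country scale-up table.
#'
#' @param countries list of scenario configurations (one per country), or a
#'   YAML path whose top-level `countries` entry holds them.
#' @param discounts discount levels.
#' @return data.frame: `country`, `year`, `discount`, `lives` (rounded),
#'   `pct` (1 decimal); attribute `"results"` holds the per-country
#'   [project_scenario()] objects.
#' @export
country_scaleup <- function(countries, discounts = c(0, 0.1, 0.2)) {
  if (is.character(countries)) {
    countries <- yaml::read_yaml(countries)$countries
  }
  results <- lapply(countries, project_scenario, discounts = discounts)
  names(results) <- vapply(results, `[[`, "", "name")
  rows <- lapply(results, function(res) {
    do.call(rbind, lapply(discounts, function(d) {
      av <- apply_discount(res$by_year$averted, d)
      data.frame(country = res$name, year = res$by_year$year, discount = d,
                 lives = round_half_away(av),
                 pct = round_half_away(100 * av / res$by_year$deaths, 1))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}
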