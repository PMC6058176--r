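# shared fixture builders -----------------------------------------------

cat6 <- c("malaria", "lrti", "diarrhoea", "urti", "malnutrition", "other")

flat_effects <- function(categories = cat6) {
  matrix(1, nrow = length(categories), ncol = 3,
         dimnames = list(categories, c("year1", "year2", "year3")))
}

# trial-emulating design with all intervention effects switched off
null_design <- function(...) {
  trial_design(true_effects = flat_effects(), ...)
}

# minimal record table for engine/compression toys (single month, two arms)
toy_records <- function(counts, all_cause,
                        categories = paste0("cat", seq_along(counts[[1]]))) {
  n <- length(all_cause)
  cnt <- do.call(rbind, counts)
  colnames(cnt) <- categories
  data.frame(cluster_id = sprintf("c%02d", seq_len(n)),
             pair_id = rep(seq_len(ceiling(n / 2)), each = 2)[seq_len(n)],
             arm = rep(c("control", "intervention"), length.out = n),
             confounder_score = 0, year = 2011, month = 1, month_index = 0,
             period = factor("baseline",
                             levels = c("baseline", "year1")),
             cnt, all_cause = all_cause, stringsAsFactors = FALSE)
}

# scenario configuration with one direct-mode intervention per cause, rigged
# so the impact fraction equals the configured value exactly: with E = AF = 1
# and C0 = 0.5, an effect r gives phi = (C0(1+r) - C0) / (1 - C0) = r
toy_scenario <- function(phis, cause_fractions, deaths_rate = 100,
                         births = 10000, years = 2012) {
  causes <- names(cause_fractions)
  list(name = "toy",
       envelope = list(years = years, u5mr = deaths_rate,
                       live_births = births,
                       cause_fractions = as.list(cause_fractions)),
       interventions = lapply(seq_along(causes), function(i) {
         list(name = paste0("iv_", causes[i]), effectiveness = 1,
              affected_fraction = 1, causes = list(causes[i]),
              coverage_mode = "direct", baseline_coverage = 0.5,
              effects = lapply(phis[[i]], function(p) {
                list(point = p, low = p, high = p)
              }))
       }))
}

published_tables <- function() {
  yaml::read_yaml(system.file("extdata", "published_tables.yaml",
                              package = "radimpact"))
}
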