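test_that("identical seeds reproduce the dataset byte for byte", {
  d <- trial_design(n_pairs = 3, baseline_rate = 200)
  a <- simulate_trial(d, seed = 11)
  b <- simulate_trial(d, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, simulate_trial(d, seed = 12)))
})

test_that("null configuration yields empirical rate ratios near 1", {
  d <- null_design(arm_offset = 0, cluster_sd = 0, confounder_effect = 0)
  rec <- simulate_trial(d, seed = 21)
  for (cat in cat6) {
    int <- sum(rec[rec$arm == "intervention", cat])
    ctl <- sum(rec[rec$arm == "control", cat])
    rr <- int / ctl
    se <- sqrt(1 / int + 1 / ctl)
    expect_lt(abs(log(rr)), 4 * se)
  }
})

test_that("configured effects show up in raw intervention/control contrasts", {
  rec <- simulate_trial(trial_design(arm_offset = 0, cluster_sd = 0,
                                     confounder_effect = 0), seed = 31)
  y1 <- rec$period == "year1"
  rr <- sum(rec[y1 & rec$arm == "intervention", "malaria"]) /
    sum(rec[y1 & rec$arm == "control", "malaria"])
  expect_equal(rr, 1.56, tolerance = 0.05)
})

test_that("all_cause mean matches baseline_rate / multiplicity at large n", {
  mult <- 1.5
  d <- trial_design(n_pairs = 100, n_months = 1,
                    period_breaks = c(year1 = 1),
                    baseline_rate = 1000, trend = 0, season = rep(0, 12),
                    arm_offset = 0, confounder_effect = 0, cluster_sd = 0,
                    true_effects = flat_effects(),
                    multiplicity_path = list(control = c(mult, mult),
                                             intervention = c(mult, mult)))
  rec <- simulate_trial(d, seed = 41)
  expect_equal(nrow(rec), 200)
  target <- 1000 / mult
  se <- sqrt((1000 / mult^2) / nrow(rec))
  expect_lt(abs(mean(rec$all_cause) - target), 3 * se + 0.5)
})

test_that("seasonal profile of simulated counts tracks the season config", {
  season <- 0.4 * sin(2 * pi * (1:12) / 12)
  d <- null_design(baseline_rate = 5000, trend = 0, season = season,
                   arm_offset = 0, confounder_effect = 0, cluster_sd = 0)
  rec <- simulate_trial(d, seed = 51)
  tot <- tapply(rec$malaria + rec$lrti + rec$other, rec$month, mean)
  expect_gt(cor(log(tot), season), 0.9)
})

test_that("period labels and calendar track the configured breaks", {
  d <- trial_design(n_pairs = 2)
  rec <- simulate_trial(d, seed = 61)
  expect_equal(unique(rec$year), 2011:2014)
  expect_true(all(rec$month_index ==
                    (rec$year - 2011) * 12 + rec$month - 1))
  expect_equal(as.character(unique(rec$period[rec$month_index < 14])),
               "baseline")
  expect_equal(as.character(unique(rec$period[rec$month_index >= 38])),
               "year3")
})

test_that("invalid configurations are rejected", {
  expect_error(trial_design(baseline_rate = 0), "baseline_rate")
  expect_error(trial_design(category_mix = c(malaria = 0.5, lrti = 0.5,
                                             diarrhoea = 0, urti = 0,
                                             malnutrition = 0, other = 0.1)),
               "sum to 1")
  expect_error(trial_design(period_breaks = c(year1 = 60)), "month range")
  expect_error(trial_design(multiplicity_path = list(control = c(0.9, 2),
                                                     intervention = c(1, 2))),
               "multiplicity")
})

test_that("multiplicity injection preserves proportions and targets", {
  rec <- toy_records(list(c(50, 30, 20)), all_cause = 100)
  # constant multiplicity 1 leaves records unchanged
  same <- inject_multiplicity(rec, list(control = c(1, 1),
                                        intervention = c(1, 1)))
  expect_identical(same, rec)
  # exact doubling is proportional
  dbl <- inject_multiplicity(rec, list(control = c(2, 2),
                                       intervention = c(2, 2)))
  expect_equal(unlist(dbl[1, c("cat1", "cat2", "cat3")], use.names = FALSE),
               c(100, 60, 40))
  # zero consultations pass through unchanged
  z <- toy_records(list(c(5, 5, 5)), all_cause = 0)
  expect_identical(inject_multiplicity(z, list(control = c(2, 2),
                                               intervention = c(2, 2))), z)
})

test_that("injected multiplicity follows the linear interpolation", {
  path <- c(1.23, 2.17)
  n_m <- 48
  rec <- do.call(rbind, lapply(seq_len(n_m) - 1L, function(m) {
    r <- toy_records(list(c(400, 200, 100)), all_cause = 700)
    r$month_index <- m
    r
  }))
  out <- inject_multiplicity(rec, list(control = path,
                                       intervention = c(1.51, 2.29)))
  m24 <- out[out$month_index == 24, ]
  expected <- path[1] + (path[2] - path[1]) * 24 / (n_m - 1)
  realized <- sum(m24[, c("cat1", "cat2", "cat3")]) / m24$all_cause
  expect_lt(abs(realized - expected), 0.5 / 700)
  # whole path, not just one month
  realized_all <- rowSums(out[, c("cat1", "cat2", "cat3")]) / out$all_cause
  expected_all <- path[1] + (path[2] - path[1]) * (seq_len(n_m) - 1) / (n_m - 1)
  expect_true(all(abs(realized_all - expected_all) <= 0.5 / 700))
})

test_that("generated multiplicity matches the configured arm paths", {
  d <- trial_design(baseline_rate = 2000)
  rec <- simulate_trial(d, seed = 71)
  expect_equal(mean_multiplicity(rec, "intervention", 0:3), 1.51,
               tolerance = 0.02)
  expect_equal(mean_multiplicity(rec, "control", 44:47), 2.17,
               tolerance = 0.02)
})

test_that("two-arm comparison under the null rejects at the nominal rate", {
  d <- null_design(arm_offset = 0, n_months = 12,
                   period_breaks = c(year1 = 12), baseline_rate = 300)
  n_rep <- 300
  rej <- logical(n_rep)
  set.seed(81)
  for (i in seq_len(n_rep)) {
    rec <- simulate_trial(d, seed = NULL)
    tot <- tapply(rec$malaria, rec$cluster_id, sum)
    arm <- tapply(rec$arm, rec$cluster_id, `[`, 1)
    # adjust for the cluster confounder before comparing arms
    conf <- tapply(rec$confounder_score, rec$cluster_id, `[`, 1)
    res <- stats::resid(stats::lm(log(tot) ~ conf))
    rej[i] <- stats::t.test(res[arm == "intervention"],
                            res[arm == "control"])$p.value < 0.05
  }
  # 0.05 +/- ~3.8 binomial SEs at 300 replicates
  expect_gt(mean(rej), 0.005)
  expect_lt(mean(rej), 0.1)
})

test_that("record CSV round-trips", {
  d <- trial_design(n_pairs = 2, baseline_rate = 50)
  rec <- simulate_trial(d, seed = 91)
  f <- tempfile(fileext = ".csv")
  write_records(rec, f)
  back <- read_records(f)
  expect_equal(back$malaria, rec$malaria)
  expect_equal(as.character(back$period), as.character(rec$period))
  expect_equal(back$confounder_score, rec$confounder_score,
               tolerance = 1e-12)
  unlink(f)
})
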