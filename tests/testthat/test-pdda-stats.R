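test_that("first-egg summaries compute mean, sample SD and counts", {
  s <- summarize_first_egg(c(64, 66, 68))
  expect_equal(s$mean_h, 66)
  expect_equal(s$sd_h, 2)
  expect_equal(s$n, 3)

  s1 <- summarize_first_egg(70)
  expect_equal(s1$mean_h, 70)
  expect_equal(s1$sd_h, 0)
  expect_equal(s1$n, 1)

  sc <- summarize_first_egg(c(64, 66, NA, 70), censored = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(sc$n, 2)
  expect_equal(sc$n_censored, 2)
  expect_error(summarize_first_egg(c(NA_real_, NA_real_)), "no uncensored")
})

test_that("simulated wildtype ISO mean matches the configured deterministic core", {
  calib <- pdda_calibration()
  obs <- simulate_pdda_assay("N2", n_iso = 1000, n_hd = 1, seed = 17)
  s <- summarize_first_egg(arm_times(obs, "ISO"))
  wt <- get_genotype("N2")
  mu <- maturation_core(wt, signal_exposure(wt, plate_environment(1), 59),
                        effective_gains(wt))
  # hourly ceiling adds half an hour on average
  se <- s$sd_h / sqrt(s$n)
  expect_lt(abs(s$mean_h - (mu + 0.5)), 3 * se + 0.05)
})

test_that("the propagated SE follows the quadrature formula", {
  iso <- summarize_first_egg(rnorm(16))
  iso$sd_h <- 2; iso$n <- 16
  hd <- summarize_first_egg(rnorm(25))
  hd$sd_h <- 1; hd$n <- 25
  ct <- iso_hd_contrast(iso, hd)
  expect_equal(ct$se_h, sqrt(4 / 16 + 1 / 25))
  expect_equal(ct$se_h, 0.5385165, tolerance = 1e-6)
})

test_that("identical arms give a null contrast", {
  x <- c(64, 65, 66, 67)
  ct <- iso_hd_contrast(x, x)
  expect_equal(ct$delta_h, 0)
  expect_gt(ct$p_value, 0.99)
})

test_that("a singleton arm propagates zero variance with a warning", {
  expect_warning(ct <- iso_hd_contrast(70, c(64, 66, 68)), "single worm")
  expect_equal(ct$se_h, sqrt(0 + 4 / 3))
})

test_that("Welch p-value matches t.test and the SE matches the bootstrap", {
  set.seed(123)
  x <- rnorm(20, 66, 2)
  y <- rnorm(24, 64.5, 1.5)
  ct <- iso_hd_contrast(x, y)
  ref <- t.test(x, y)
  expect_equal(ct$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(ct$t_statistic, unname(ref$statistic), tolerance = 1e-12)

  boot <- replicate(10000, mean(sample(x, replace = TRUE)) -
                      mean(sample(y, replace = TRUE)))
  expect_lt(abs(ct$se_h / sd(boot) - 1), 0.1)
})

test_that("Pdda percent evaluates the normalization formula exactly", {
  wt_iso <- c(67, 68, 69)
  wt_hd <- c(64, 65, 66)
  # a strain indistinguishable from wildtype scores exactly 100
  expect_identical(pdda_percent(wt_iso, wt_hd, wt_iso, wt_hd)$pdda_percent, 100)
  # zero mutant effect scores exactly 0
  same <- c(79, 80, 81)
  expect_identical(pdda_percent(same, same, wt_iso, wt_hd)$pdda_percent, 0)
  # worked example: (12 / 3) * (68 / 80) * 100
  res <- pdda_percent(c(79, 80, 81), c(67, 68, 69), wt_iso, wt_hd)
  expect_equal(res$pdda_percent, 340)
  expect_error(pdda_percent(wt_iso, wt_hd, same, same), "undefined")
})

test_that("Pdda percent is linear in the mutant time difference", {
  wt_iso <- summarize_first_egg(c(67, 68, 69))
  wt_hd <- summarize_first_egg(c(64, 65, 66))
  base <- 80
  pct <- vapply(c(1, 2, 4, 8), function(d) {
    mut_hd <- summarize_first_egg(base - d + c(-1, 0, 1))
    mut_iso <- summarize_first_egg(base + c(-1, 0, 1))
    pdda_percent(mut_iso, mut_hd, wt_iso, wt_hd)$pdda_percent
  }, numeric(1))
  expect_equal(pct / pct[1], c(1, 2, 4, 8))
})

test_that("treatment effects are percents of the untreated Pdda", {
  expect_equal(treatment_effect_percent(80, 80), 100)
  expect_equal(treatment_effect_percent(0, 80), 0)
  expect_equal(treatment_effect_percent(40, 80), 50)
  expect_error(treatment_effect_percent(40, 0), "undefined")
})

test_that("Bonferroni adjustment caps at one and validates input", {
  expect_equal(bonferroni_adjust(c(0.01, 0.04)), c(0.02, 0.08))
  expect_equal(bonferroni_adjust(0.3), 0.3)
  expect_equal(bonferroni_adjust(c(0.9, 0.9, 0.9)), c(1, 1, 1))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("whole-plate first-egg time is an order-statistic of plate size", {
  # minimum of one worm is the per-worm mean
  one <- plate_first_event_time(function(n) rnorm(n, 66, 1), 1,
                                reps = 4000, seed = 1)
  expect_lt(abs(one$expected_min_h - 66), 4 * one$se_h + 0.01)

  # shifted exponential: E[min of two] = offset + mean/2
  two <- plate_first_event_time(function(n) 60 + rexp(n, rate = 1), 2,
                                reps = 6000, seed = 2)
  expect_lt(abs(two$expected_min_h - 60.5), 4 * two$se_h + 0.01)

  # apparent onset drops strictly with plate size on a fixed normal
  mins <- vapply(c(1, 10, 100), function(n) {
    plate_first_event_time(function(k) rnorm(k, 66, 2), n,
                           reps = 3000, seed = 3)$expected_min_h
  }, numeric(1))
  expect_true(all(diff(mins) < -0.5))
})
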