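test_that("signal deposition is linear in worms and time and rejects bad input", {
  expect_equal(signal_level(100, 59, 1), 5900)
  expect_equal(signal_level(1, 59, 1), 59)
  expect_equal(signal_level(0, 17, 3), 0)
  expect_error(signal_level(-1, 10, 1), "must be finite and >= 0")
  expect_error(signal_level(10, NA, 1), "must be finite and >= 0")
})

test_that("the epistasis rule table encodes the observed genetics", {
  env0 <- plate_environment(1)
  env_da <- plate_environment(1, exogenous_da_nM = 100)
  wt <- effective_gains(get_genotype("N2"), env0)
  expect_equal(wt, list(g_X = 1, g_A = 1, g_I = 1))

  # cilium-defective worms cannot perceive ascarosides but respond to X
  osm6 <- effective_gains(get_genotype("osm-6"), env0)
  expect_equal(osm6$g_A, 0)
  expect_equal(osm6$g_X, 1)

  # DA silences the X response on a DAF-12(+) background ...
  expect_lt(effective_gains(get_genotype("N2"), env_da)$g_X, 0.1)
  # ... restores it in nhr-8 worms ...
  expect_equal(effective_gains(get_genotype("nhr-8"), env_da)$g_X, 1)
  expect_lt(effective_gains(get_genotype("nhr-8"), env0)$g_X, 0.2)
  # ... has no effect without DAF-12 ...
  expect_equal(effective_gains(get_genotype("daf-12"), env_da)$g_X,
               effective_gains(get_genotype("daf-12"), env0)$g_X)
  # ... and leaves the enhanced double-mutant response unchanged
  nd <- effective_gains(get_genotype("nhr-8;daf-12"), env0)
  nd_da <- effective_gains(get_genotype("nhr-8;daf-12"), env_da)
  expect_identical(nd, nd_da)
  expect_gt(nd$g_X, 1)

  # insulin-pathway loss in either direction silences the response
  expect_lt(effective_gains(get_genotype("daf-2"), env0)$g_X, 0.1)
  expect_lt(effective_gains(get_genotype("daf-16"), env0)$g_X, 0.1)
})

test_that("undeclared flag combinations fall back to wildtype gains with a warning", {
  daf9_alone <- genotype_profile("daf-9", da_biosynthesis = FALSE)
  expect_warning(g <- effective_gains(daf9_alone, plate_environment(1)),
                 "wildtype gains")
  expect_equal(g$g_X, 1)
})

test_that("rule table is total over all flag combinations", {
  flags <- expand.grid(asc = c(TRUE, FALSE), cil = c(TRUE, FALSE),
                       nhr8 = c(TRUE, FALSE), daf12 = c(TRUE, FALSE),
                       da_bio = c(TRUE, FALSE),
                       ins = c("wildtype", "daf2_lf", "daf16_lf"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(flags))) {
    g <- genotype_profile("combo", ascaroside_production = flags$asc[i],
                          ciliated_chemosensation = flags$cil[i],
                          nhr8_functional = flags$nhr8[i],
                          daf12_functional = flags$daf12[i],
                          da_biosynthesis = flags$da_bio[i],
                          insulin_state = flags$ins[i])
    gains <- suppressWarnings(effective_gains(g, plate_environment(1)))
    expect_true(all(is.finite(unlist(gains))))
    expect_gte(gains$g_X, 0)
  }
})

test_that("deterministic core recovers the baseline exactly at zero signal", {
  calib <- pdda_calibration()
  zero <- list(X_level = 0, A_level = 0)
  wt <- get_genotype("N2")
  gains <- effective_gains(wt, plate_environment(1))
  expect_identical(maturation_core(wt, zero, gains, calib),
                   wt$baseline_maturation_h)
  eat2 <- get_genotype("eat-2")
  expect_identical(maturation_core(eat2, zero, effective_gains(eat2), calib),
                   eat2$baseline_maturation_h / eat2$feeding_rate_factor)
})

test_that("with zero X gain the core is independent of X exposure", {
  calib <- pdda_calibration()
  wt <- get_genotype("N2")
  gains <- list(g_X = 0, g_A = 1, g_I = 1)
  t1 <- maturation_core(wt, list(X_level = 0, A_level = 100), gains, calib)
  t2 <- maturation_core(wt, list(X_level = 9000, A_level = 100), gains, calib)
  expect_identical(t1, t2)
})

test_that("deterministic wildtype ISO-HD gap sits in the 2-5 h band", {
  calib <- pdda_calibration()
  wt <- get_genotype("N2")
  gains <- effective_gains(wt)
  proto <- assay_protocol()
  t_iso <- maturation_core(wt, signal_exposure(wt, plate_environment(1),
                                               proto$transfer_time_h), gains)
  t_hd <- maturation_core(wt, signal_exposure(wt, plate_environment(100),
                                              proto$transfer_time_h), gains)
  expect_gt(t_iso - t_hd, 2)
  expect_lt(t_iso - t_hd, 5)
})

test_that("maturation time is monotone in density and in ascaroside dose", {
  calib <- pdda_calibration()
  wt <- get_genotype("N2")
  gains <- effective_gains(wt)
  core_at_n <- vapply(1:150, function(n) {
    maturation_core(wt, signal_exposure(wt, plate_environment(n), 59), gains)
  }, numeric(1))
  expect_true(all(diff(core_at_n) <= 1e-10))

  core_at_dose <- vapply(seq(0, 800, 50), function(nm) {
    env <- plate_environment(100, exogenous_ascr_nM = nm)
    maturation_core(wt, signal_exposure(wt, env, 59), gains)
  }, numeric(1))
  expect_true(all(diff(core_at_dose) >= -1e-10))
})

test_that("simulations are reproducible from their seed", {
  a <- simulate_pdda_assay("N2", n_iso = 15, n_hd = 30, seed = 11)
  b <- simulate_pdda_assay("N2", n_iso = 15, n_hd = 30, seed = 11)
  expect_identical(a, b)
  p1 <- simulate_preconditioned_assay("daf-22", "daf-22", n = 10, seed = 4)
  p2 <- simulate_preconditioned_assay("daf-22", "daf-22", n = 10, seed = 4)
  expect_identical(p1, p2)
  l1 <- simulate_lifespan(10, 10, "II", n_worms = 20, seed = 3)
  l2 <- simulate_lifespan(10, 10, "II", n_worms = 20, seed = 3)
  expect_identical(l1, l2)
})

test_that("simulated assays show the density phenotype with genotype ordering", {
  wt <- simulate_pdda_assay("N2", n_iso = 100, n_hd = 100, seed = 21)
  m_wt <- arm_means(wt)
  expect_lt(m_wt["hd"], m_wt["iso"])

  d22 <- simulate_pdda_assay("daf-22", n_iso = 100, n_hd = 100, seed = 22)
  m_d22 <- arm_means(d22)
  expect_gt(m_d22["iso"] - m_d22["hd"], m_wt["iso"] - m_wt["hd"])
})

test_that("scoring snaps first-egg times to whole hours not before scoring starts", {
  obs <- simulate_pdda_assay("daf-22", n_iso = 50, n_hd = 200, seed = 31)
  t <- obs$first_egg_time_h[!obs$censored]
  expect_true(all(t >= 60))
  expect_true(all(t == round(t)))
})

test_that("pre-conditioned plates accelerate isolated worms part-way to HD", {
  obs <- simulate_preconditioned_assay("daf-22", "daf-22", n = 100, seed = 41)
  m <- tapply(obs$first_egg_time_h[!obs$censored],
              obs$condition[!obs$censored], mean)
  expect_lt(m["HD_preincubated_ISO"], m["ISO"])
  expect_gt(m["HD_preincubated_ISO"], m["HD"])

  # double mutant develops about as fast as its HD arm on conditioned plates
  nd <- simulate_preconditioned_assay("nhr-8;daf-12", "daf-22", n = 100,
                                      seed = 42)
  m_nd <- tapply(nd$first_egg_time_h[!nd$censored],
                 nd$condition[!nd$censored], mean)
  expect_lt(abs(m_nd["HD_preincubated_ISO"] - m_nd["HD"]), 1.5)
})

test_that("null pre-conditioning reproduces the plain ISO arm draw for draw", {
  calib <- pdda_calibration()
  calib$preconditioning$carryover <- 0
  proto <- assay_protocol()
  env_iso <- plate_environment(1)
  plain <- pddasim:::simulate_arm(get_genotype("daf-22"), env_iso, proto, 30,
                                  "ISO", calib, seed = 55)
  obs <- simulate_preconditioned_assay("daf-22", "daf-22", proto, n = 30,
                                       seed = 55, calib = calib)
  pre <- obs[obs$condition == "HD_preincubated_ISO", ]
  # same exposure, but arm seeds differ; compare the generating environment
  env_equal <- identical(
    signal_exposure(get_genotype("daf-22"), env_iso, 59, calib),
    signal_exposure(get_genotype("daf-22"),
                    plate_environment(1, preconditioned_X = 0,
                                      preconditioned_A = 0), 59, calib))
  expect_true(env_equal)
  expect_equal(mean(pre$first_egg_time_h, na.rm = TRUE),
               mean(plain$first_egg_time_h, na.rm = TRUE), tolerance = 0.02)
})

test_that("lifespan depends on larval but not adult density", {
  # protocol I: same larval history, different adult densities, same seed
  l1 <- simulate_lifespan(1, 1, "I", n_worms = 60, seed = 61)
  l50 <- simulate_lifespan(50, 50, "I", n_worms = 60, seed = 61)
  expect_identical(l1$event_day, l50$event_day)

  # protocol II: lifelong isolation outlives lifelong crowding
  m1 <- sim_ls_mean(1, 1, "II", seed = 62)
  m50 <- sim_ls_mean(50, 50, "II", seed = 62)
  expect_gt(m1, m50)
})

test_that("dafachronic acid shortens lifespan only for isolated larvae", {
  m_iso_da <- mean(vapply(1:5, function(s)
    sim_ls_mean(1, 1, "II", seed = 70 + s, da_nM = 100), numeric(1)))
  m_iso <- mean(vapply(1:5, function(s)
    sim_ls_mean(1, 1, "II", seed = 80 + s), numeric(1)))
  expect_lt(m_iso_da, m_iso - 2)

  m_20_da <- mean(vapply(1:5, function(s)
    sim_ls_mean(20, 20, "II", seed = 70 + s, da_nM = 100), numeric(1)))
  m_20 <- mean(vapply(1:5, function(s)
    sim_ls_mean(20, 20, "II", seed = 80 + s), numeric(1)))
  expect_lt(abs(m_20_da - m_20), 1)
})
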