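# shared helpers for the simulation tests

# uncensored first-egg times of one arm of a worm-observation table
arm_times <- function(obs, condition) {
  x <- obs[obs$condition == condition & !obs$censored, "first_egg_time_h"]
  x[!is.na(x)]
}

# mean first-egg times of the two arms of a simulated assay
arm_means <- function(obs) {
  c(iso = mean(arm_times(obs, "ISO")), hd = mean(arm_times(obs, "HD")))
}

# ISO - HD difference of one simulated assay for a genotype, one seed
sim_delta <- function(genotype, seed, n = 100, ...) {
  obs <- simulate_pdda_assay(genotype, n_iso = n, n_hd = n, seed = seed, ...)
  iso_hd_contrast(arm_times(obs, "ISO"), arm_times(obs, "HD"))$delta_h
}

# KM mean lifespan after exclusions for one simulated cohort
sim_ls_mean <- function(larval, adult, protocol, seed, da_nM = 0, n = 100) {
  rec <- simulate_lifespan(larval, adult, protocol, da_nM = da_nM,
                           n_worms = n, seed = seed)
  km_estimate(apply_exclusions(rec)$event_day)$mean_day
}

# Gompertz death-day sampler used for null calibration checks
rgompertz <- function(n, a = 3.31e-4, b = 0.3) {
  log(1 - b * log(stats::runif(n)) / a) / b
}

# label-permutation p-value for the Welch statistic
perm_p_welch <- function(x, y, B = 20000) {
  tstat <- function(u, v) {
    abs(mean(u) - mean(v)) /
      sqrt(stats::var(u) / length(u) + stats::var(v) / length(v))
  }
  obs <- tstat(x, y)
  z <- c(x, y)
  na <- length(x)
  hits <- 0
  for (b in seq_len(B)) {
    idx <- sample.int(length(z), na)
    if (tstat(z[idx], z[-idx]) >= obs - 1e-12) hits <- hits + 1
  }
  hits / B
}

# label-permutation p-value for the log-rank chi-square
perm_p_logrank <- function(a, b, B = 20000) {
  obs <- pddasim:::logrank_chi2(a, b)
  z <- c(a, b)
  na <- length(a)
  hits <- 0
  for (i in seq_len(B)) {
    idx <- sample.int(length(z), na)
    if (pddasim:::logrank_chi2(z[idx], z[-idx]) >= obs - 1e-12) hits <- hits + 1
  }
  hits / B
}
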