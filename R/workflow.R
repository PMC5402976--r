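worm_obs_columns <- c("worm_id", "plate_id", "genotype", "condition",
                      "first_egg_time_h", "censored", "stage_at_obs", "hatched")
lifespan_columns <- c("worm_id", "larval_density", "adult_density", "protocol",
                      "da_treated", "event_day", "event_type")
report_columns <- c("experiment", "genotype", "treatment", "metric", "value",
                    "se", "p", "p_adj", "seed")

check_schema <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(df)
}

# small rolling hash so outputs can embed a fingerprint of the configuration
# without a cryptographic dependency
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_with_meta <- function(df, path, meta = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
}

#' Write / read worm-observation CSV
#'
#' Tidy UTF-8 CSV with one row per worm and the fixed column schema of the
#' simulator output. Censored first-egg times are written as empty cells
#' alongside the logical `censored` column, so the encoding survives a round
#' trip. Optional `# key: value` metadata lines (seed, configuration hash)
#' precede the header.
#'
#' @param observations Worm-observation `data.frame`.
#' @param path Output file.
#' @param meta Character vector of metadata lines to embed.
#' @return `path`, invisibly (writer); the validated `data.frame` (reader).
#' @export
write_worm_observations <- function(observations, path, meta = character()) {
  check_schema(observations, worm_obs_columns, "worm observation table")
  write_with_meta(observations[worm_obs_columns], path, meta)
  invisible(path)
}

#' @rdname write_worm_observations
#' @export
read_worm_observations <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        na.strings = "")
  check_schema(df, worm_obs_columns, "worm observation file")
  df$censored <- as.logical(df$censored)
  df$hatched <- as.logical(df$hatched)
  df$first_egg_time_h <- as.numeric(df$first_egg_time_h)
  df
}

#' Write / read lifespan-record CSV
#'
#' @param records Lifespan-record `data.frame`.
#' @inheritParams write_worm_observations
#' @export
write_lifespan_records <- function(records, path, meta = character()) {
  check_schema(records, lifespan_columns, "lifespan record table")
  write_with_meta(records[lifespan_columns], path, meta)
  invisible(path)
}

#' @rdname write_lifespan_records
#' @export
read_lifespan_records <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        na.strings = "")
  check_schema(df, lifespan_columns, "lifespan record file")
  df$da_treated <- as.logical(df$da_treated)
  df
}

#' Experiment suite configuration
#'
#' Declares the in-silico reproduction of the full experiment suite: the
#' genotype panel assayed for Pdda, the compound-treatment arms, the density
#' ladders of the two lifespan protocols, per-arm worm numbers, replicate
#' count and the master seed from which every arm seed is derived.
#'
#' @param genotypes Strain names from [genotype_library()] assayed against
#'   the parallel wildtype.
#' @param ascr_nM,da_nM Compound doses used in treatment arms.
#' @param lifespan_densities Density ladder for both lifespan protocols.
#' @param n_iso,n_hd Worms per ISO / HD arm of each egg-laying assay.
#' @param n_staged Worms staged per arm at the staging time.
#' @param n_lifespan Worms per lifespan group.
#' @param n_replicates Independent biological replicates per Pdda estimate
#'   (the reported Pdda is their unweighted mean).
#' @param master_seed Integer master seed.
#' @return An `experiment_suite_config` list.
#' @export
experiment_suite_config <- function(genotypes = c("daf-22", "dhs-28", "osm-6",
                                                  "tax-4", "odr-3", "mec-4",
                                                  "eat-2", "egl-4", "daf-2",
                                                  "daf-16", "nhr-8", "daf-12",
                                                  "nhr-8;daf-12",
                                                  "daf-9;daf-12"),
                                    ascr_nM = 400, da_nM = 100,
                                    lifespan_densities = c(1, 10, 20, 50),
                                    n_iso = 25, n_hd = 100, n_staged = 60,
                                    n_lifespan = 75, n_replicates = 3,
                                    master_seed = 20170410) {
  lib_names <- names(genotype_library())
  bad <- setdiff(genotypes, lib_names)
  if (length(bad)) stop("unknown genotype(s): ", paste(bad, collapse = ", "))
  structure(list(genotypes = genotypes, ascr_nM = ascr_nM, da_nM = da_nM,
                 lifespan_densities = lifespan_densities, n_iso = n_iso,
                 n_hd = n_hd, n_staged = n_staged, n_lifespan = n_lifespan,
                 n_replicates = n_replicates, master_seed = master_seed),
            class = "experiment_suite_config")
}

arm_times <- function(obs, condition) {
  x <- obs[obs$condition == condition & !obs$censored, "first_egg_time_h"]
  x[!is.na(x)]
}

# One Pdda estimate (replicate-averaged) for a genotype/treatment against its
# parallel wildtype run under the same treatment history.
run_pdda_arm <- function(genotype, config, seed_base, ascr_nM = 0, da_nM = 0,
                         calib) {
  env_of <- function(n) plate_environment(n, exogenous_ascr_nM = ascr_nM,
                                          exogenous_da_nM = da_nM)
  per_rep <- lapply(seq_len(config$n_replicates), function(r) {
    s_mut <- derive_seed(seed_base, 10 * r + 1)
    s_wt <- derive_seed(seed_base, 10 * r + 2)
    mut <- simulate_pdda_assay(genotype, env_iso = env_of(1),
                               env_hd = env_of(config$n_hd),
                               n_iso = config$n_iso, n_hd = config$n_hd,
                               seed = s_mut, calib = calib)
    wt <- simulate_pdda_assay("N2", n_iso = config$n_iso, n_hd = config$n_hd,
                              seed = s_wt, calib = calib)
    pdda_percent(arm_times(mut, "ISO"), arm_times(mut, "HD"),
                 arm_times(wt, "ISO"), arm_times(wt, "HD"))
  })
  pcts <- vapply(per_rep, function(p) p$pdda_percent, numeric(1))
  deltas <- vapply(per_rep, function(p) p$mutant_contrast$delta_h, numeric(1))
  ses <- vapply(per_rep, function(p) p$mutant_contrast$se_h, numeric(1))
  ps <- vapply(per_rep, function(p) p$mutant_contrast$p_value, numeric(1))
  list(pdda_percent = mean(pcts), delta_h = mean(deltas),
       se_h = sqrt(mean(ses^2) / length(ses)), p = min(1, min(ps) * length(ps)))
}

report_row <- function(experiment, genotype, treatment, metric, value,
                       se = NA_real_, p = NA_real_, seed = NA_real_) {
  data.frame(experiment = experiment, genotype = genotype,
             treatment = treatment, metric = metric, value = value, se = se,
             p = p, p_adj = NA_real_, seed = seed, stringsAsFactors = FALSE)
}

#' Reproduce the full in-silico experiment suite
#'
#' Runs the complete set of simulated experiments under one master seed: the
#' wildtype reference assay, the mutant Pdda panel with Bonferroni-adjusted
#' contrasts, the compound-treatment arms, the wildtype staging comparison,
#' and the lifespan density ladders of both protocols with and without
#' dafachronic acid. Also evaluates the qualitative epistasis expectations
#' (which mutants enhance, abolish, or leave Pdda unchanged) and reports a
#' pass flag for each.
#'
#' @param config An [experiment_suite_config()].
#' @param calib A [pdda_calibration()].
#' @return List with `report` (long-format `data.frame`: experiment,
#'   genotype, treatment, metric, value, se, p, p_adj, seed),
#'   `epistasis` (`data.frame` of qualitative checks with pass flags), and
#'   `config_hash`.
#' @examples
#' \donttest{
#' suite <- reproduce_suite(experiment_suite_config(
#'   genotypes = "daf-22", lifespan_densities = c(1, 50),
#'   n_lifespan = 40, n_replicates = 2))
#' subset(suite$report, metric == "pdda_percent")
#' }
#' @export
reproduce_suite <- function(config = experiment_suite_config(),
                            calib = pdda_calibration()) {
  ms <- config$master_seed
  rows <- list()

  # wildtype reference row: the strain normalized against itself is 100
  # percent by definition, so the same simulated assay serves as both arms
  wt_reps <- lapply(seq_len(config$n_replicates), function(r) {
    obs <- simulate_pdda_assay("N2", n_iso = config$n_iso,
                               n_hd = config$n_hd,
                               seed = derive_seed(ms, 10 + r), calib = calib)
    pdda_percent(arm_times(obs, "ISO"), arm_times(obs, "HD"),
                 arm_times(obs, "ISO"), arm_times(obs, "HD"))
  })
  wt_delta <- vapply(wt_reps, function(p) p$mutant_contrast$delta_h, numeric(1))
  wt_se <- vapply(wt_reps, function(p) p$mutant_contrast$se_h, numeric(1))
  wt_p <- vapply(wt_reps, function(p) p$mutant_contrast$p_value, numeric(1))
  rows[[length(rows) + 1]] <-
    report_row("pdda_panel", "N2", "none", "pdda_percent",
               mean(vapply(wt_reps, function(p) p$pdda_percent, numeric(1))),
               sqrt(mean(wt_se^2) / length(wt_se)),
               min(1, min(wt_p) * length(wt_p)), ms)
  rows[[length(rows) + 1]] <-
    report_row("pdda_panel", "N2", "none", "delta_h", mean(wt_delta),
               sqrt(mean(wt_se^2) / length(wt_se)),
               min(1, min(wt_p) * length(wt_p)), ms)

  for (i in seq_along(config$genotypes)) {
    g <- config$genotypes[i]
    run <- run_pdda_arm(g, config, derive_seed(ms, 100 + i), calib = calib)
    rows[[length(rows) + 1]] <-
      report_row("pdda_panel", g, "none", "pdda_percent", run$pdda_percent,
                 run$se_h, run$p, ms)
    rows[[length(rows) + 1]] <-
      report_row("pdda_panel", g, "none", "delta_h", run$delta_h, run$se_h,
                 run$p, ms)
  }

  treatments <- list(
    list(genotype = "N2", ascr = config$ascr_nM, da = 0, label = "ascr#2"),
    list(genotype = "N2", ascr = 0, da = config$da_nM, label = "dafa#3"),
    list(genotype = "daf-22", ascr = config$ascr_nM, da = 0, label = "ascr#2"),
    list(genotype = "daf-22", ascr = 0, da = config$da_nM, label = "dafa#3"),
    list(genotype = "nhr-8", ascr = 0, da = config$da_nM, label = "dafa#3"),
    list(genotype = "nhr-8;daf-12", ascr = 0, da = config$da_nM,
         label = "dafa#3"))
  for (i in seq_along(treatments)) {
    tr <- treatments[[i]]
    run <- run_pdda_arm(tr$genotype, config, derive_seed(ms, 200 + i),
                        ascr_nM = tr$ascr, da_nM = tr$da, calib = calib)
    rows[[length(rows) + 1]] <-
      report_row("compound", tr$genotype, tr$label, "pdda_percent",
                 run$pdda_percent, run$se_h, run$p, ms)
  }

  # staging at the fixed clock time
  st_obs <- simulate_pdda_assay("N2", n_iso = config$n_staged,
                                n_hd = config$n_staged,
                                seed = derive_seed(ms, 300), calib = calib)
  st <- staging_result(st_obs[st_obs$condition == "ISO", ],
                       st_obs[st_obs$condition == "HD", ],
                       stage_scale(calib = calib))
  rows[[length(rows) + 1]] <-
    report_row("staging", "N2", "none", "lead_h", st$lead_h,
               p = st$p_value, seed = ms)

  # lifespan ladders
  for (proto in c("I", "II")) {
    for (d in config$lifespan_densities) {
      rec <- simulate_lifespan(d, d, proto, da_nM = 0,
                               n_worms = config$n_lifespan,
                               seed = derive_seed(ms, 400 + d +
                                                    ifelse(proto == "I", 0, 1000)),
                               calib = calib)
      km <- km_estimate(apply_exclusions(rec)$event_day)
      rows[[length(rows) + 1]] <-
        report_row("lifespan", "N2", sprintf("protocol %s, %d wpp", proto, d),
                   "mean_lifespan_d", km$mean_day, seed = ms)
    }
  }
  rec_da <- simulate_lifespan(1, 1, "II", da_nM = config$da_nM,
                              n_worms = config$n_lifespan,
                              seed = derive_seed(ms, 500), calib = calib)
  km_da <- km_estimate(apply_exclusions(rec_da)$event_day)
  rows[[length(rows) + 1]] <-
    report_row("lifespan", "N2", "protocol II, 1 wpp + dafa#3",
               "mean_lifespan_d", km_da$mean_day, seed = ms)

  report <- do.call(rbind, rows)
  is_panel <- report$experiment %in% c("pdda_panel", "compound") &
    report$metric == "pdda_percent"
  report$p_adj[is_panel] <- bonferroni_adjust(report$p[is_panel])

  epi <- epistasis_sheet(config, calib)
  list(report = report, epistasis = epi, config_hash = config_hash(config))
}

#' Qualitative epistasis expectations
#'
#' Evaluates the ordered comparisons that summarize the genetics of the
#' density response: enhancement in ascaroside-free and cilium-defective
#' strains, no change in general-chemotaxis and mechanosensory strains,
#' suppression by ascarosides and dafachronic acid, dependence on nhr-8 with
#' DA-reversal, enhancement in the nhr-8;daf-12 double, and wildtype-like
#' behaviour of DA-free daf-9;daf-12 worms. Each Pdda value is simulated at
#' `n_hd` worms per arm under seeds derived from the master seed; "similar"
#' and "abolished" are judged against bands of +/- 30 percentage points
#' around 100 and 0 (about two simulation standard errors at 100 worms per
#' arm).
#'
#' @param config An [experiment_suite_config()].
#' @param calib A [pdda_calibration()].
#' @return `data.frame` with columns `comparison`, `observed`, `expected`,
#'   `pass`.
#' @export
epistasis_sheet <- function(config = experiment_suite_config(),
                            calib = pdda_calibration()) {
  ms <- derive_seed(config$master_seed, 900)
  cfg <- config
  cfg$n_iso <- cfg$n_hd      # equal, well-powered arms for the ordered checks
  one <- function(idx, genotype, ascr = 0, da = 0) {
    run_pdda_arm(genotype, cfg, derive_seed(ms, idx), ascr_nM = ascr,
                 da_nM = da, calib = calib)$pdda_percent
  }
  p_d22 <- one(1, "daf-22")
  p_osm6 <- one(2, "osm-6")
  p_odr3 <- one(3, "odr-3")
  p_mec4 <- one(4, "mec-4")
  p_ascr <- one(5, "N2", ascr = cfg$ascr_nM)
  p_da <- one(6, "N2", da = cfg$da_nM)
  p_nhr8 <- one(7, "nhr-8")
  p_nhr8_da <- one(8, "nhr-8", da = cfg$da_nM)
  p_nd <- one(9, "nhr-8;daf-12")
  p_dd <- one(10, "daf-9;daf-12")
  near <- function(x, centre, tol = 30) abs(x - centre) <= tol
  checks <- list(
    list("Pdda(daf-22) > Pdda(WT)", p_d22, "> 130", p_d22 > 130),
    list("Pdda(osm-6) > Pdda(WT)", p_osm6, "> 130", p_osm6 > 130),
    list("Pdda(odr-3) ~ Pdda(WT)", p_odr3, "100 +/- 30", near(p_odr3, 100)),
    list("Pdda(mec-4) ~ Pdda(WT)", p_mec4, "100 +/- 30", near(p_mec4, 100)),
    list("Pdda(WT + ascr#2) < Pdda(WT)", p_ascr, "< 70", p_ascr < 70),
    list("Pdda(WT + dafa#3) ~ 0", p_da, "0 +/- 30", near(p_da, 0)),
    list("Pdda(nhr-8) ~ 0", p_nhr8, "0 +/- 30", near(p_nhr8, 0)),
    list("Pdda(nhr-8 + dafa#3) ~ Pdda(WT)", p_nhr8_da, "100 +/- 30",
         near(p_nhr8_da, 100)),
    list("Pdda(nhr-8;daf-12) ~ Pdda(daf-22)", p_nd,
         sprintf("%.0f +/- 30%%", p_d22), abs(p_nd - p_d22) <= 0.3 * p_d22),
    list("Pdda(daf-9;daf-12) ~ Pdda(WT)", p_dd, "100 +/- 30", near(p_dd, 100)))
  data.frame(comparison = vapply(checks, `[[`, character(1), 1),
             observed = round(vapply(checks, `[[`, numeric(1), 2), 1),
             expected = vapply(checks, `[[`, character(1), 3),
             pass = vapply(checks, `[[`, logical(1), 4),
             stringsAsFactors = FALSE)
}

#' Write the long-format report table
#'
#' @param suite Result of [reproduce_suite()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(suite, path) {
  check_schema(suite$report, report_columns, "report table")
  write_with_meta(suite$report, path,
                  meta = c(paste0("config_hash: ", suite$config_hash)))
  invisible(path)
}
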