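#' Plate environment
#'
#' Describes the chemical environment a cohort of worms develops in: how many
#' worms share the plate, exogenous compound doses, and any signal deposited
#' by previous occupants of a pre-conditioned plate.
#'
#' @param n_worms Worms per plate (>= 1).
#' @param exogenous_ascr_nM Synthetic ascaroside dose (400 nM in compound
#'   assays).
#' @param exogenous_da_nM Synthetic dafachronic acid dose (100 nM in compound
#'   assays).
#' @param preconditioned_X,preconditioned_A Signal units already present on
#'   the plate from prior occupants (A is 0 when the conditioning worms were
#'   ascaroside-free).
#' @return An object of class `plate_environment`.
#' @export
plate_environment <- function(n_worms = 1, exogenous_ascr_nM = 0,
                              exogenous_da_nM = 0, preconditioned_X = 0,
                              preconditioned_A = 0) {
  vals <- c(n_worms, exogenous_ascr_nM, exogenous_da_nM,
            preconditioned_X, preconditioned_A)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("plate_environment values must be finite and >= 0")
  }
  if (n_worms < 1) stop("n_worms must be >= 1")
  structure(list(n_worms = n_worms,
                 exogenous_ascr_nM = exogenous_ascr_nM,
                 exogenous_da_nM = exogenous_da_nM,
                 preconditioned_X = preconditioned_X,
                 preconditioned_A = preconditioned_A),
            class = "plate_environment")
}

#' Assay protocol
#'
#' Clock times of the egg-laying assay. Under protocol B worms develop on
#' ISO or HD plates until `transfer_time_h`, are singled onto fresh plates,
#' and are then scored hourly for the first laid egg from `scoring_start_h`.
#' Protocol A scores the original plate directly (see
#' [plate_first_event_time()] for the order-statistic confound this causes).
#'
#' @param protocol_id `"A"` or `"B"`.
#' @param transfer_time_h Hours at which worms are singled (protocol B).
#' @param scoring_start_h First hourly scoring time.
#' @param scoring_interval_h Scoring interval, hours.
#' @param staging_time_h Clock time of the microscopy staging observation.
#' @param hd_plate_size Default worms per high-density plate.
#' @return An object of class `assay_protocol`.
#' @export
assay_protocol <- function(protocol_id = c("B", "A"), transfer_time_h = 59,
                           scoring_start_h = 60, scoring_interval_h = 1,
                           staging_time_h = 52, hd_plate_size = 100) {
  protocol_id <- match.arg(protocol_id)
  if (protocol_id == "B" && scoring_start_h <= transfer_time_h) {
    stop("scoring_start_h must be after transfer_time_h for protocol B")
  }
  if (scoring_interval_h <= 0) stop("scoring_interval_h must be > 0")
  structure(list(protocol_id = protocol_id,
                 transfer_time_h = transfer_time_h,
                 scoring_start_h = scoring_start_h,
                 scoring_interval_h = scoring_interval_h,
                 staging_time_h = staging_time_h,
                 hd_plate_size = hd_plate_size),
            class = "assay_protocol")
}

#' Deposited signal level
#'
#' Linear accumulation of an excreted signal: a plate occupied by `n_worms`
#' worms for `elapsed_h` hours at deposition rate `deposition_rate` carries
#' `deposition_rate * n_worms * elapsed_h` units. Exogenous and
#' pre-conditioned contributions are added by the caller.
#'
#' @param n_worms Number of worms depositing (>= 0).
#' @param elapsed_h Occupancy duration, hours.
#' @param deposition_rate Units per worm-hour.
#' @return Signal units.
#' @examples
#' signal_level(100, 59, 1) # 5900
#' @export
signal_level <- function(n_worms, elapsed_h, deposition_rate) {
  vals <- c(n_worms, elapsed_h, deposition_rate)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("signal_level arguments must be finite and >= 0")
  }
  deposition_rate * n_worms * elapsed_h
}

#' Signal exposure of a cohort at transfer time
#'
#' Sums deposited, exogenous and pre-conditioned contributions of the
#' accelerating signal (X) and of ascarosides (A), evaluated at the moment
#' worms are singled onto fresh plates. Exposure is frozen at that point:
#' nothing accumulates on the single-worm scoring plates fast enough to
#' matter before egg laying begins.
#'
#' @param genotype A [genotype_profile()]; ascaroside-free strains deposit
#'   no A.
#' @param env A [plate_environment()].
#' @param elapsed_h Occupancy time over which deposition accrues.
#' @param calib A [pdda_calibration()].
#' @return List with `X_level` and `A_level` in signal units.
#' @export
signal_exposure <- function(genotype, env, elapsed_h,
                            calib = pdda_calibration()) {
  dep <- calib$deposition
  X <- signal_level(env$n_worms, elapsed_h, dep$rate_X) + env$preconditioned_X
  A_dep <- if (genotype$ascaroside_production) {
    signal_level(env$n_worms, elapsed_h, dep$rate_A)
  } else 0
  A <- A_dep + env$preconditioned_A + env$exogenous_ascr_nM * dep$ascr_nM_to_units
  list(X_level = X, A_level = A)
}

#' Pathway gains of the push-pull model
#'
#' Phenomenological rule table translating a genotype's pathway flags and the
#' dafachronic acid (DA) dose on the plate into three unitless gains:
#' `g_X`, the response to the accelerating signal; `g_A`, perception of
#' ascarosides (requires intact sensory cilia); and `g_I`, the strength with
#' which perceived ascarosides inhibit the X response. The table encodes the
#' observed epistasis: insulin-pathway loss or receptor-saturating DA on a
#' DAF-12(+) background silences the X response; nhr-8 loss silences it but
#' DA restores it; joint nhr-8;daf-12 loss enhances it (and decouples it from
#' ascaroside inhibition, so DA and ascaroside feedback have no effect);
#' daf-12 loss alone only slightly reduces it.
#'
#' @param genotype A [genotype_profile()].
#' @param env A [plate_environment()] (only the DA dose is consulted).
#' @param calib A [pdda_calibration()].
#' @return List with numeric `g_X`, `g_A`, `g_I`.
#' @examples
#' effective_gains(get_genotype("N2"), plate_environment(1))
#' @export
effective_gains <- function(genotype, env = plate_environment(1),
                            calib = pdda_calibration()) {
  m <- calib$maturation
  da_on <- env$exogenous_da_nM >= calib$deposition$da_threshold_nM
  g_A <- if (genotype$ciliated_chemosensation) 1 else 0

  if (!genotype$nhr8_functional && !genotype$daf12_functional) {
    # joint loss: enhanced X response, released from ascaroside inhibition,
    # and insensitive to DA (no receptor left to liganded)
    return(list(g_X = m$g_X_enhanced, g_A = g_A, g_I = 0))
  }
  if (!genotype$da_biosynthesis && genotype$daf12_functional && !da_on) {
    # DA-free worms with intact DAF-12 arrest as dauer-like larvae unless
    # rescued; outside the model, fall back to wildtype gains
    warning("genotype '", genotype$name, "' lacks DA biosynthesis with ",
            "functional DAF-12 and no exogenous DA; using wildtype gains")
    return(list(g_X = 1, g_A = g_A, g_I = g_A))
  }
  g_X <- if (genotype$insulin_state != "wildtype") {
    m$g_X_abolished
  } else if (!genotype$nhr8_functional) {
    if (da_on) 1 else m$g_X_nhr8
  } else if (!genotype$daf12_functional) {
    m$g_X_daf12                         # DA has no effect without DAF-12
  } else if (da_on) {
    m$g_X_abolished
  } else 1
  list(g_X = g_X, g_A = g_A, g_I = g_A)
}

#' Deterministic maturation time
#'
#' The noise-free core of the generative model:
#' \deqn{T = \frac{T_0}{f}\Big(1 + \delta_A g_A \mathrm{sat}(A, K_A)
#'   - \delta_X g_X \frac{\mathrm{sat}(X, K_X)}{1 + g_I g_A A / K_I}\Big)}
#' with \eqn{\mathrm{sat}(u, K) = u/(u+K)}. The accelerating signal X shortens
#' maturation; perceived ascarosides both add a small direct delay and, via
#' the inhibition term, damp the response to X. At zero exposure the core
#' returns exactly `baseline_maturation_h / feeding_rate_factor`.
#'
#' @param genotype A [genotype_profile()].
#' @param exposure List with `X_level`, `A_level` (see [signal_exposure()]).
#' @param gains List with `g_X`, `g_A`, `g_I` (see [effective_gains()]).
#' @param calib A [pdda_calibration()].
#' @return Hours, a single positive number.
#' @export
maturation_core <- function(genotype, exposure, gains,
                            calib = pdda_calibration()) {
  m <- calib$maturation
  X <- exposure$X_level
  A <- exposure$A_level
  if (any(c(X, A) < 0)) stop("exposure must be >= 0")
  inhib <- 1 / (1 + gains$g_I * gains$g_A * A / m$K_I)
  t0 <- genotype$baseline_maturation_h / genotype$feeding_rate_factor
  T_det <- t0 * (1 + m$delta_A * gains$g_A * saturating(A, m$K_A) -
                   m$delta_X * gains$g_X * saturating(X, m$K_X) * inhib)
  if (T_det <= 0) {
    stop("calibration yields non-positive maturation time (",
         format(T_det), " h) for genotype '", genotype$name, "'")
  }
  T_det
}

#' Stochastic maturation times
#'
#' Draws per-worm maturation times: the deterministic core plus Gaussian
#' noise (SD from the genotype profile), truncated at four SD to keep draws
#' physical.
#'
#' @inheritParams maturation_core
#' @param n Number of worms to draw.
#' @return Numeric vector of hours, length `n`.
#' @export
maturation_time <- function(genotype, exposure, gains, n = 1,
                            calib = pdda_calibration()) {
  mu <- maturation_core(genotype, exposure, gains, calib)
  sd <- genotype$maturation_noise_sd_h
  if (is.null(sd) || is.na(sd)) sd <- calib$maturation$noise_sd_default_h
  eps <- stats::rnorm(n, 0, sd)
  eps <- pmin(pmax(eps, -4 * sd), 4 * sd)
  mu + eps
}

# Snap a raw maturation time onto the hourly scoring grid: first egg can only
# be recorded at whole scoring hours, never before scoring begins.
score_first_egg <- function(t_raw, protocol) {
  grid <- ceiling(t_raw / protocol$scoring_interval_h) * protocol$scoring_interval_h
  pmax(grid, protocol$scoring_start_h)
}

# Assign an ordinal larval stage at the staging observation time by mapping
# each worm onto the reference developmental timeline: a worm that matures in
# T_i hours is, at clock time t, as far along as a reference worm at
# t * T_ref / T_i. Stage boundaries are midpoints between map entries.
stage_at <- function(t_obs, t_mature, calib) {
  map <- unlist(calib$staging$stage_time_map)
  t_ref <- calib$protocol$reference_maturation_h
  equiv <- t_obs * t_ref / t_mature
  bounds <- c(-Inf, (map[-length(map)] + map[-1]) / 2, Inf)
  names(map)[findInterval(equiv, bounds)]
}

new_worm_observation <- function(worm_id, plate_id, genotype, condition,
                                 first_egg_time_h, censored, stage_at_obs,
                                 hatched) {
  data.frame(worm_id = worm_id, plate_id = plate_id, genotype = genotype,
             condition = condition, first_egg_time_h = first_egg_time_h,
             censored = censored, stage_at_obs = stage_at_obs,
             hatched = hatched, stringsAsFactors = FALSE)
}

simulate_arm <- function(genotype, env, protocol, n, condition, calib, seed,
                         plate_prefix = condition) {
  with_seed(seed, {
    gains <- effective_gains(genotype, env, calib)
    exposure <- signal_exposure(genotype, env, protocol$transfer_time_h, calib)
    t_raw <- maturation_time(genotype, exposure, gains, n, calib)
    hatched <- stats::runif(n) < calib$protocol$hatch_rate
    first_egg <- score_first_egg(t_raw, protocol)
    first_egg[!hatched] <- NA_real_
    stage <- stage_at(protocol$staging_time_h, t_raw, calib)
    stage[!hatched] <- NA_character_
    plate_id <- if (env$n_worms > 1) {
      paste0(plate_prefix, "-p", ((seq_len(n) - 1L) %/% env$n_worms) + 1L)
    } else {
      paste0(plate_prefix, "-p", seq_len(n))
    }
    new_worm_observation(
      worm_id = paste0(plate_prefix, "-w", seq_len(n)),
      plate_id = plate_id, genotype = genotype$name, condition = condition,
      first_egg_time_h = first_egg, censored = !hatched,
      stage_at_obs = stage, hatched = hatched)
  })
}

#' Simulate an ISO versus HD egg-laying assay
#'
#' Generates per-worm first-egg records for one protocol-B assay: `n_iso`
#' worms reared one per plate and `n_hd` worms reared on high-density plates
#' (`env_hd$n_worms` worms each), all singled at the transfer time and scored
#' hourly from the scoring start. Exposure to plate signals is evaluated at
#' transfer and frozen. Unhatched embryos (at one minus the calibrated hatch
#' rate) are flagged and carry no egg time. A fixed seed makes the output
#' fully reproducible.
#'
#' @param genotype A [genotype_profile()] or a strain name in
#'   [genotype_library()].
#' @param env_iso,env_hd [plate_environment()]s of the two rearing arms.
#' @param protocol An [assay_protocol()].
#' @param n_iso,n_hd Worms per arm.
#' @param seed Integer seed fixing all randomness.
#' @param calib A [pdda_calibration()].
#' @return A `data.frame` of worm observations (one row per worm) with
#'   columns `worm_id`, `plate_id`, `genotype`, `condition`,
#'   `first_egg_time_h`, `censored`, `stage_at_obs`, `hatched`.
#' @examples
#' obs <- simulate_pdda_assay("N2", n_iso = 20, n_hd = 20, seed = 1)
#' aggregate(first_egg_time_h ~ condition, obs, mean)
#' @export
simulate_pdda_assay <- function(genotype,
                                env_iso = plate_environment(1),
                                env_hd = NULL,
                                protocol = assay_protocol(),
                                n_iso = 25, n_hd = 100, seed = NULL,
                                calib = pdda_calibration()) {
  if (is.character(genotype)) genotype <- get_genotype(genotype)
  if (is.null(env_hd)) env_hd <- plate_environment(protocol$hd_plate_size)
  stopifnot(n_iso >= 1, n_hd >= 1)
  iso <- simulate_arm(genotype, env_iso, protocol, n_iso, "ISO", calib,
                      derive_seed(seed, 1L))
  hd <- simulate_arm(genotype, env_hd, protocol, n_hd, "HD", calib,
                     derive_seed(seed, 2L))
  rbind(iso, hd)
}

#' Simulate an assay on pre-conditioned plates
#'
#' Isolated worms are reared on plates previously occupied by a high-density
#' cohort of `preconditioner` worms (removed at L4, before egg laying), so
#' they experience the deposited accelerating signal -- and ascarosides only
#' if the conditioning strain produces them -- from the start, despite being
#' alone. Returns the pre-conditioned ISO arm together with plain ISO and HD
#' arms of the same genotype for comparison.
#'
#' @param genotype Assayed strain ([genotype_profile()] or name).
#' @param preconditioner Strain that conditioned the plates.
#' @param protocol An [assay_protocol()].
#' @param n Worms in the pre-conditioned arm (plain arms match).
#' @param seed Integer seed.
#' @param calib A [pdda_calibration()].
#' @return A `data.frame` of worm observations with conditions `ISO`, `HD`
#'   and `HD_preincubated_ISO`.
#' @export
simulate_preconditioned_assay <- function(genotype, preconditioner = genotype,
                                          protocol = assay_protocol(),
                                          n = 25, seed = NULL,
                                          calib = pdda_calibration()) {
  if (is.character(genotype)) genotype <- get_genotype(genotype)
  if (is.character(preconditioner)) preconditioner <- get_genotype(preconditioner)
  pc <- calib$preconditioning
  deposited <- signal_level(pc$occupancy, pc$removal_h, calib$deposition$rate_X) *
    pc$carryover
  pre_A <- if (preconditioner$ascaroside_production) {
    signal_level(pc$occupancy, pc$removal_h, calib$deposition$rate_A) * pc$carryover
  } else 0
  env_pre <- plate_environment(1, preconditioned_X = deposited,
                               preconditioned_A = pre_A)
  plain <- simulate_pdda_assay(genotype, protocol = protocol, n_iso = n,
                               n_hd = n, seed = seed, calib = calib)
  pre <- simulate_arm(genotype, env_pre, protocol, n, "HD_preincubated_ISO",
                      calib, derive_seed(seed, 3L))
  rbind(plain, pre)
}

#' Simulate an adult lifespan assay
#'
#' Death days (from young adulthood) follow a Gompertz law whose baseline
#' hazard increases with crowding experienced during the larval phase and,
#' at low larval density only, with dafachronic acid exposure. Density during
#' adulthood has no effect on the death-time distribution. Under protocol I
#' worms are reared at high density and distributed onto assay plates as
#' young adults, so their larval density is the calibrated rearing density
#' regardless of `adult_density`; under protocol II the assay density applies
#' from the egg onward. A small calibrated fraction of worms is lost to
#' internal hatching, exploding through the vulva, or crawling off the plate.
#'
#' @param larval_density Worms per plate during development (protocol II);
#'   ignored under protocol I, where rearing density is the calibrated value.
#' @param adult_density Worms per plate during adulthood (no lifespan effect;
#'   recorded in the output).
#' @param protocol `"I"` (densities imposed from young adulthood) or `"II"`
#'   (from egg).
#' @param da_nM Dafachronic acid dose on the plates, nM.
#' @param n_worms Cohort size.
#' @param seed Integer seed.
#' @param calib A [pdda_calibration()].
#' @return A `data.frame` of lifespan records: `worm_id`, `larval_density`,
#'   `adult_density`, `protocol`, `da_treated`, `event_day`, `event_type`.
#' @examples
#' ls1 <- simulate_lifespan(1, 1, "II", n_worms = 30, seed = 1)
#' table(ls1$event_type)
#' @export
simulate_lifespan <- function(larval_density, adult_density = larval_density,
                              protocol = c("II", "I"), da_nM = 0,
                              n_worms = 100, seed = NULL,
                              calib = pdda_calibration()) {
  protocol <- match.arg(protocol)
  stopifnot(larval_density >= 1, adult_density >= 1, n_worms >= 1, da_nM >= 0)
  ls <- calib$lifespan
  d_larval <- if (protocol == "I") ls$protocol_I_larval_density else larval_density
  a <- ls$gompertz_a0 * exp(ls$beta * saturating(d_larval, ls$K_L))
  a <- a * (1 + ls$c_da * saturating(da_nM, ls$K_da) *
              exp(-(d_larval - 1) / ls$da_density_decay))
  b <- ls$gompertz_b
  with_seed(seed, {
    u <- stats::runif(n_worms)
    t_death <- log(1 - b * log(u) / a) / b
    event_day <- ceiling(t_death)
    rates <- unlist(ls$exclusion_rates)
    event_type <- sample(c("death", names(rates)), n_worms, replace = TRUE,
                         prob = c(1 - sum(rates), rates))
    # non-death events interrupt follow-up somewhere before death
    interrupted <- event_type != "death"
    if (any(interrupted)) {
      event_day[interrupted] <-
        ceiling(stats::runif(sum(interrupted)) * t_death[interrupted])
    }
    data.frame(worm_id = sprintf("ls-w%d", seq_len(n_worms)),
               larval_density = d_larval, adult_density = adult_density,
               protocol = protocol, da_treated = da_nM > 0,
               event_day = pmax(event_day, 1), event_type = event_type,
               stringsAsFactors = FALSE)
  })
}
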