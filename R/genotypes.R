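#' Construct a genotype profile
#'
#' A genotype profile holds the baseline life-history parameters of a strain
#' together with the boolean pathway flags that drive the phenomenological
#' epistasis rule table (see [effective_gains()]). Flags default to the
#' wildtype (N2) state, so a mutant is declared by switching off the pathway
#' it lacks.
#'
#' @param name Strain label.
#' @param baseline_maturation_h Mean time to first egg laying of an isolated
#'   worm in the absence of any plate signal, hours after egg transfer.
#' @param maturation_noise_sd_h Between-worm SD of maturation time, hours.
#' @param ascaroside_production `FALSE` for peroxisomal beta-oxidation mutants
#'   (daf-22, dhs-28), which excrete no ascarosides.
#' @param ciliated_chemosensation `FALSE` for cilium-defective strains
#'   (osm-6, tax-4), which cannot perceive ascarosides.
#' @param general_chemotaxis `FALSE` for odr-3; no effect on Pdda.
#' @param mechanosensation `FALSE` for mec-4; no effect on Pdda.
#' @param nhr8_functional,daf12_functional Nuclear hormone receptor status.
#' @param da_biosynthesis `FALSE` for daf-9, which makes no dafachronic acids.
#' @param insulin_state One of `"wildtype"`, `"daf2_lf"`, `"daf16_lf"`.
#' @param feeding_rate_factor Relative pharyngeal pumping rate (< 1 for
#'   eat-2); divides the baseline maturation time, so it rescales absolute
#'   developmental time without changing normalized Pdda.
#' @param egg_retention `TRUE` for egl-4; carried as metadata, no effect.
#' @return An object of class `genotype_profile`.
#' @examples
#' daf22 <- genotype_profile("daf-22", baseline_maturation_h = 76,
#'                           ascaroside_production = FALSE)
#' @export
genotype_profile <- function(name,
                             baseline_maturation_h = 68,
                             maturation_noise_sd_h = 2,
                             ascaroside_production = TRUE,
                             ciliated_chemosensation = TRUE,
                             general_chemotaxis = TRUE,
                             mechanosensation = TRUE,
                             nhr8_functional = TRUE,
                             daf12_functional = TRUE,
                             da_biosynthesis = TRUE,
                             insulin_state = c("wildtype", "daf2_lf", "daf16_lf"),
                             feeding_rate_factor = 1,
                             egg_retention = FALSE) {
  insulin_state <- match.arg(insulin_state)
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(baseline_maturation_h) || baseline_maturation_h <= 0) {
    stop("baseline_maturation_h must be > 0")
  }
  if (!is.numeric(maturation_noise_sd_h) || maturation_noise_sd_h < 0) {
    stop("maturation_noise_sd_h must be >= 0")
  }
  if (!is.numeric(feeding_rate_factor) || feeding_rate_factor <= 0) {
    stop("feeding_rate_factor must be > 0")
  }
  structure(
    list(name = name,
         baseline_maturation_h = baseline_maturation_h,
         maturation_noise_sd_h = maturation_noise_sd_h,
         ascaroside_production = isTRUE(ascaroside_production),
         ciliated_chemosensation = isTRUE(ciliated_chemosensation),
         general_chemotaxis = isTRUE(general_chemotaxis),
         mechanosensation = isTRUE(mechanosensation),
         nhr8_functional = isTRUE(nhr8_functional),
         daf12_functional = isTRUE(daf12_functional),
         da_biosynthesis = isTRUE(da_biosynthesis),
         insulin_state = insulin_state,
         feeding_rate_factor = feeding_rate_factor,
         egg_retention = isTRUE(egg_retention)),
    class = "genotype_profile"
  )
}

#' @export
print.genotype_profile <- function(x, ...) {
  cat("<genotype_profile> ", x$name,
      "  T0 = ", x$baseline_maturation_h, " h (sd ",
      x$maturation_noise_sd_h, " h)\n", sep = "")
  off <- c(ascarosides = !x$ascaroside_production,
           cilia = !x$ciliated_chemosensation,
           chemotaxis = !x$general_chemotaxis,
           mechanosensation = !x$mechanosensation,
           `nhr-8` = !x$nhr8_functional,
           `daf-12` = !x$daf12_functional,
           `DA biosynthesis` = !x$da_biosynthesis)
  if (any(off)) cat("  lost: ", paste(names(off)[off], collapse = ", "), "\n", sep = "")
  if (x$insulin_state != "wildtype") cat("  insulin:", x$insulin_state, "\n")
  invisible(x)
}

#' Built-in genotype panel
#'
#' The strain panel used throughout the simulated experiment suite. Baseline
#' maturation times are calibration choices within the bands typical for each
#' strain class: wildtype-like strains near 68 h; strains with strongly
#' enhanced density responses (ascaroside-free or cilium-defective strains and
#' the nhr-8;daf-12 double mutant) near 76 h, so that even their fastest
#' high-density worms mature after scoring begins at 60 h; eat-2 slowed via
#' its feeding-rate factor.
#'
#' @return Named list of [genotype_profile()] objects.
#' @examples
#' names(genotype_library())
#' @export
genotype_library <- function() {
  list(
    N2 = genotype_profile("N2", 68, 1.5),
    `daf-22` = genotype_profile("daf-22", 76, 2, ascaroside_production = FALSE),
    `dhs-28` = genotype_profile("dhs-28", 76, 2, ascaroside_production = FALSE),
    `osm-6` = genotype_profile("osm-6", 76, 2, ciliated_chemosensation = FALSE),
    `tax-4` = genotype_profile("tax-4", 76, 2, ciliated_chemosensation = FALSE),
    `odr-3` = genotype_profile("odr-3", 68, 2, general_chemotaxis = FALSE),
    `mec-4` = genotype_profile("mec-4", 68, 2, mechanosensation = FALSE),
    `eat-2` = genotype_profile("eat-2", 68, 2, feeding_rate_factor = 0.85),
    `egl-4` = genotype_profile("egl-4", 68, 2, egg_retention = TRUE),
    `daf-2` = genotype_profile("daf-2", 74, 2, insulin_state = "daf2_lf"),
    `daf-16` = genotype_profile("daf-16", 67, 2, insulin_state = "daf16_lf"),
    `nhr-8` = genotype_profile("nhr-8", 70, 2, nhr8_functional = FALSE),
    `daf-12` = genotype_profile("daf-12", 70, 2, daf12_functional = FALSE),
    `nhr-8;daf-12` = genotype_profile("nhr-8;daf-12", 76, 2,
                                      nhr8_functional = FALSE,
                                      daf12_functional = FALSE),
    `daf-9;daf-12` = genotype_profile("daf-9;daf-12", 72, 2,
                                      da_biosynthesis = FALSE,
                                      daf12_functional = FALSE),
    `ins-11` = genotype_profile("ins-11", 68, 2)
  )
}

#' Look up a genotype profile by name
#'
#' @param name Strain label present in [genotype_library()].
#' @return A [genotype_profile()].
#' @export
get_genotype <- function(name) {
  lib <- genotype_library()
  if (!name %in% names(lib)) {
    stop("unknown genotype '", name, "'; available: ",
         paste(names(lib), collapse = ", "))
  }
  lib[[name]]
}
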