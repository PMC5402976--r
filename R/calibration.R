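#' Load the model calibration
#'
#' Reads the versioned calibration file shipped with the package (or a user
#' supplied file with the same structure). The calibration fixes every
#' constant of the generative model: the push-pull maturation core, signal
#' deposition rates, plate pre-conditioning, the stage-to-hours map and the
#' Gompertz lifespan parameters.
#'
#' @param path Path to a YAML calibration file. Defaults to the calibration
#'   shipped with the package.
#' @return A named list of calibration blocks (class `pdda_calibration`).
#' @examples
#' calib <- pdda_calibration()
#' calib$maturation$delta_X
#' @export
pdda_calibration <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "calibration.yaml", package = "pddasim")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("calibration file not found: ", path)
  }
  calib <- yaml::read_yaml(path)
  required <- c("maturation", "deposition", "preconditioning", "protocol",
                "staging", "lifespan")
  missing <- setdiff(required, names(calib))
  if (length(missing)) {
    stop("calibration file is missing blocks: ", paste(missing, collapse = ", "))
  }
  structure(calib, class = "pdda_calibration")
}

# Michaelis-type saturating response, sat(0) = 0, sat -> 1 as u -> Inf.
saturating <- function(u, K) u / (u + K)

# Run expr with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Derive a child seed from a master seed
#'
#' Deterministic child seeds (kept below 2^31) so that one master seed can
#' drive many independently seeded simulation arms.
#'
#' @param seed Master seed (or `NULL`, which propagates).
#' @param index Arm index.
#' @return A numeric seed, or `NULL` if `seed` is `NULL`.
#' @export
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 7919 + 104729 * index) %% 2147483647
}
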