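#' Ordinal larval stage scale
#'
#' The ordered developmental stages scored at the fixed-clock-time staging
#' observation (L1 through the L4.1--L4.9 sub-stages, young adult, adult),
#' together with a map from each stage to the typical hours since egg
#' transfer at which an isolated wildtype worm shows it. The default map is
#' read from the package calibration; L4 sub-stage times are linear between
#' the L4.2 (52 h) and L4.5 (57 h) anchors.
#'
#' @param stage_time_map Named numeric vector (stage label -> hours),
#'   strictly increasing in stage order. Defaults to the calibrated map.
#' @param calib A [pdda_calibration()] (used only when `stage_time_map` is
#'   `NULL`).
#' @return A `stage_scale`: list with `labels` (ordered) and `hours`.
#' @examples
#' stage_scale()$labels
#' @export
stage_scale <- function(stage_time_map = NULL, calib = pdda_calibration()) {
  if (is.null(stage_time_map)) {
    stage_time_map <- unlist(calib$staging$stage_time_map)
  }
  if (is.null(names(stage_time_map)) || any(!nzchar(names(stage_time_map)))) {
    stop("stage_time_map must be a named numeric vector")
  }
  if (any(diff(stage_time_map) <= 0)) {
    stop("stage_time_map must be strictly increasing along the stage order")
  }
  structure(list(labels = names(stage_time_map),
                 hours = unname(stage_time_map)),
            class = "stage_scale")
}

#' Stage counts of one assay arm
#'
#' Tabulates observed ordinal stages over the full stage scale (empty stages
#' count zero). Worms without a stage record (e.g. unhatched) are dropped.
#'
#' @param observations Worm-observation `data.frame` (see
#'   [simulate_pdda_assay()]) or a character vector of stage labels.
#' @param scale A [stage_scale()].
#' @return Named integer vector of counts, one per stage label.
#' @export
stage_distribution <- function(observations, scale = stage_scale()) {
  stages <- if (is.data.frame(observations)) observations$stage_at_obs
            else observations
  stages <- stages[!is.na(stages)]
  unknown <- setdiff(unique(stages), scale$labels)
  if (length(unknown)) {
    stop("unknown stage label(s): ", paste(unknown, collapse = ", "))
  }
  table(factor(stages, levels = scale$labels))
}

#' Compare two ordinal stage distributions
#'
#' Wilcoxon rank-sum test on the ordinal stage scale with midrank handling of
#' ties (normal approximation with continuity correction), testing whether
#' one arm is developmentally ahead of the other at the staging time.
#'
#' @param iso_counts,hd_counts Stage counts from [stage_distribution()] (on
#'   the same scale), or raw observation inputs accepted by it.
#' @param scale A [stage_scale()].
#' @return List with `statistic` (rank-sum W), `p_value`, and per-arm totals.
#' @export
compare_stage_distributions <- function(iso_counts, hd_counts,
                                        scale = stage_scale()) {
  as_counts <- function(x) {
    if (is.table(x) || (is.numeric(x) && !is.null(names(x)))) {
      cnt <- x[scale$labels]
      cnt[is.na(cnt)] <- 0
      cnt
    } else {
      stage_distribution(x, scale)
    }
  }
  iso <- as_counts(iso_counts)
  hd <- as_counts(hd_counts)
  n_iso <- sum(iso)
  n_hd <- sum(hd)
  if (n_iso == 0 || n_hd == 0) stop("both arms must contain staged worms")
  rank_of <- seq_along(scale$labels)
  x <- rep(rank_of, iso)
  y <- rep(rank_of, hd)
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_iso = n_iso, n_hd = n_hd)
}

#' Developmental lead in hours
#'
#' Converts the stage shift between two arms at the fixed staging time into
#' hours of development, using the stage-to-hours map: the mean mapped time
#' of the HD arm minus the ISO arm. Positive values mean HD worms are ahead.
#'
#' @param iso_obs,hd_obs Worm observations or stage-label vectors of the two
#'   arms.
#' @param scale A [stage_scale()].
#' @return Hours (a single number).
#' @examples
#' developmental_lead_h(rep("L4.2", 5), rep("L4.5", 5))  # 5 h on default map
#' @export
developmental_lead_h <- function(iso_obs, hd_obs, scale = stage_scale()) {
  mean_mapped <- function(obs) {
    counts <- stage_distribution(obs, scale)
    if (sum(counts) == 0) stop("arm contains no staged worms")
    sum(scale$hours * as.numeric(counts)) / sum(counts)
  }
  mean_mapped(hd_obs) - mean_mapped(iso_obs)
}

#' Full staging comparison
#'
#' Convenience wrapper returning stage counts per arm, the rank-sum
#' comparison and the hours-of-lead estimate in one object.
#'
#' @inheritParams developmental_lead_h
#' @return A `staging_result`: list with `iso_counts`, `hd_counts`,
#'   `lead_h`, `test_statistic`, `p_value`.
#' @export
staging_result <- function(iso_obs, hd_obs, scale = stage_scale()) {
  iso_counts <- stage_distribution(iso_obs, scale)
  hd_counts <- stage_distribution(hd_obs, scale)
  cmp <- compare_stage_distributions(iso_counts, hd_counts, scale)
  structure(list(iso_counts = iso_counts, hd_counts = hd_counts,
                 lead_h = developmental_lead_h(iso_obs, hd_obs, scale),
                 test_statistic = cmp$statistic, p_value = cmp$p_value),
            class = "staging_result")
}

#' @export
print.staging_result <- function(x, ...) {
  cat(sprintf("<staging_result> HD lead %.2f h, rank-sum p = %.3g\n",
              x$lead_h, x$p_value))
  invisible(x)
}
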