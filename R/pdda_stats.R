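#' Summarize first-egg times
#'
#' Mean, sample SD and count of the uncensored first-egg times of one assay
#' arm. Censored worms (and unhatched embryos, which carry no egg time) are
#' excluded; their count is kept on the summary for reporting.
#'
#' @param times Numeric vector of first-egg times, hours. May contain `NA`
#'   for worms without an observed egg.
#' @param censored Logical vector marking right-censored/unhatched worms;
#'   defaults to `is.na(times)`.
#' @param condition Optional arm label carried through to reports.
#' @return A `first_egg_summary`: list with `mean_h`, `sd_h`, `n`,
#'   `n_censored`, `condition`.
#' @examples
#' summarize_first_egg(c(64, 66, 68))
#' @export
summarize_first_egg <- function(times, censored = is.na(times),
                                condition = NA_character_) {
  stopifnot(length(censored) == length(times))
  keep <- !censored & !is.na(times)
  if (!any(keep)) stop("no uncensored first-egg times to summarize")
  x <- times[keep]
  structure(list(mean_h = mean(x),
                 sd_h = if (length(x) > 1) stats::sd(x) else 0,
                 n = length(x),
                 n_censored = sum(!keep),
                 condition = condition),
            class = "first_egg_summary")
}

#' @export
print.first_egg_summary <- function(x, ...) {
  cat(sprintf("<first_egg_summary>%s mean %.2f h, sd %.2f h, n = %d (%d censored)\n",
              if (is.na(x$condition)) "" else paste0(" [", x$condition, "]"),
              x$mean_h, x$sd_h, x$n, x$n_censored))
  invisible(x)
}

#' ISO minus HD contrast of mean first-egg times
#'
#' The difference in mean time to first egg laying between isolated and
#' high-density worms, its propagated standard error
#' \eqn{\sqrt{s_{ISO}^2/N_{ISO} + s_{HD}^2/N_{HD}}}, and the p-value of an
#' unequal-variance (Welch) two-sample t-test computed from the summary
#' statistics.
#'
#' @param iso,hd [summarize_first_egg()] summaries (or numeric vectors of raw
#'   times, which are summarized first).
#' @return An `iso_hd_contrast`: list with `delta_h`, `se_h`, `df`,
#'   `t_statistic`, `p_value` and the two summaries.
#' @examples
#' iso_hd_contrast(c(66, 68, 70, 67), c(63, 64, 65, 63))
#' @export
iso_hd_contrast <- function(iso, hd) {
  if (is.numeric(iso)) iso <- summarize_first_egg(iso, condition = "ISO")
  if (is.numeric(hd)) hd <- summarize_first_egg(hd, condition = "HD")
  stopifnot(inherits(iso, "first_egg_summary"), inherits(hd, "first_egg_summary"))
  if (iso$n == 1 || hd$n == 1) {
    warning("an arm has a single worm; its variance contribution is zero")
  }
  v_iso <- iso$sd_h^2 / iso$n
  v_hd <- hd$sd_h^2 / hd$n
  se <- sqrt(v_iso + v_hd)
  delta <- iso$mean_h - hd$mean_h
  if (se > 0) {
    t_stat <- delta / se
    df <- (v_iso + v_hd)^2 /
      (v_iso^2 / max(iso$n - 1, 1) + v_hd^2 / max(hd$n - 1, 1))
    p <- 2 * stats::pt(-abs(t_stat), df)
  } else {
    t_stat <- if (delta == 0) 0 else sign(delta) * Inf
    df <- NA_real_
    p <- if (delta == 0) 1 else 0
  }
  structure(list(delta_h = delta, se_h = se, df = df, t_statistic = t_stat,
                 p_value = p, iso = iso, hd = hd),
            class = "iso_hd_contrast")
}

#' @export
print.iso_hd_contrast <- function(x, ...) {
  cat(sprintf("<iso_hd_contrast> delta %.2f h (se %.3f), Welch p = %.3g\n",
              x$delta_h, x$se_h, x$p_value))
  invisible(x)
}

#' Pdda percent of the parallel wildtype effect
#'
#' The population density-dependent acceleration metric: the mutant's ISO
#' minus HD difference in mean first-egg time, normalized to the difference
#' seen in the parallel wildtype experiment and to the mutant's own absolute
#' developmental time,
#' \deqn{\mathrm{Pdda}\,[\%] = \frac{t_{ISO}^{mut} - t_{HD}^{mut}}
#'   {t_{ISO}^{wt} - t_{HD}^{wt}} \cdot \frac{t_{ISO}^{wt}}{t_{ISO}^{mut}}
#'   \cdot 100.}
#' The second factor makes the metric invariant to strain-wide rescaling of
#' developmental time (e.g. slow-feeding strains), so a strain identical to
#' wildtype scores exactly 100.
#'
#' @param mut_iso,mut_hd,wt_iso,wt_hd [summarize_first_egg()] summaries (or
#'   raw numeric time vectors) of the four assay arms.
#' @return A `pdda_result`: list with `pdda_percent`, `mutant_contrast`,
#'   `wildtype_contrast` and `adjusted_p` (`NA` until multiplicity
#'   correction is applied across a panel).
#' @examples
#' wt_iso <- c(67, 68, 69); wt_hd <- c(64, 65, 66)
#' pdda_percent(wt_iso, wt_hd, wt_iso, wt_hd)$pdda_percent # exactly 100
#' @export
pdda_percent <- function(mut_iso, mut_hd, wt_iso, wt_hd) {
  mutant <- iso_hd_contrast(mut_iso, mut_hd)
  wildtype <- iso_hd_contrast(wt_iso, wt_hd)
  if (wildtype$delta_h == 0) {
    stop("wildtype ISO and HD means are equal; Pdda percent is undefined ",
         "(zero reference effect)")
  }
  if (mutant$iso$mean_h <= 0 || wildtype$iso$mean_h <= 0) {
    stop("mean first-egg times must be positive")
  }
  pct <- mutant$delta_h / wildtype$delta_h *
    wildtype$iso$mean_h / mutant$iso$mean_h * 100
  structure(list(pdda_percent = pct, mutant_contrast = mutant,
                 wildtype_contrast = wildtype, adjusted_p = NA_real_),
            class = "pdda_result")
}

#' @export
print.pdda_result <- function(x, ...) {
  cat(sprintf("<pdda_result> %.1f%% of wildtype Pdda (mutant delta %.2f h, wildtype delta %.2f h)\n",
              x$pdda_percent, x$mutant_contrast$delta_h,
              x$wildtype_contrast$delta_h))
  invisible(x)
}

#' Treatment effect as percent of the untreated Pdda
#'
#' Compound assays report the change in Pdda as
#' `100 * treated / untreated` percent of the effect in untreated worms.
#'
#' @param pdda_treated,pdda_untreated [pdda_percent()] results (or bare
#'   percentages).
#' @return Percent of the untreated effect.
#' @export
treatment_effect_percent <- function(pdda_treated, pdda_untreated) {
  val <- function(x) if (inherits(x, "pdda_result")) x$pdda_percent else x
  treated <- val(pdda_treated)
  untreated <- val(pdda_untreated)
  if (untreated == 0) stop("untreated Pdda is zero; treatment effect undefined")
  100 * treated / untreated
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` for each of `m` p-values, as used for the mutant-panel and
#' compound comparisons.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length.
#' @export
bonferroni_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Expected first-egg time on a multi-worm plate
#'
#' On a plate scored for the first egg laid by any of its `n_worms` worms,
#' the recorded time is the minimum of n per-worm times: the apparent onset
#' of egg laying drops with plate size even if individual worms are
#' unchanged. This Monte-Carlo estimator of \eqn{E[\min_{i \le n} T_i]}
#' quantifies that order-statistic confound of whole-plate scoring.
#'
#' @param per_worm_sampler Function of one argument `n` returning `n` i.i.d.
#'   per-worm first-egg times.
#' @param n_worms Worms per plate.
#' @param reps Monte-Carlo replicates.
#' @param seed Integer seed.
#' @return List with `expected_min_h`, `se_h`, `n_worms`, `reps`.
#' @examples
#' plate_first_event_time(function(n) rnorm(n, 66, 2), n_worms = 10,
#'                        reps = 2000, seed = 1)$expected_min_h
#' @export
plate_first_event_time <- function(per_worm_sampler, n_worms, reps = 5000,
                                   seed = NULL) {
  stopifnot(is.function(per_worm_sampler), n_worms >= 1, reps >= 1)
  with_seed(seed, {
    mins <- vapply(seq_len(reps),
                   function(i) min(per_worm_sampler(n_worms)), numeric(1))
    list(expected_min_h = mean(mins),
         se_h = stats::sd(mins) / sqrt(reps),
         n_worms = n_worms, reps = reps)
  })
}
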