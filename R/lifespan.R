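#' Apply lifespan exclusion rules
#'
#' Worms lost to internal hatching, exploding, or crawling off the plate are
#' excluded from lifespan analysis (not censored): only death events are
#' retained. Alternatively the non-death events can be kept as right-censored
#' observations.
#'
#' @param records Lifespan-record `data.frame` (see [simulate_lifespan()]).
#' @param mode `"exclude"` (default) drops non-death records; `"censor"`
#'   keeps them flagged as censored.
#' @return The retained records with a logical `censored` column; attribute
#'   `excluded_counts` tabulates the dropped categories.
#' @export
apply_exclusions <- function(records, mode = c("exclude", "censor")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(records), "event_type" %in% names(records))
  non_death <- records$event_type != "death"
  excluded <- table(records$event_type[non_death])
  if (mode == "exclude") {
    out <- records[!non_death, , drop = FALSE]
    out$censored <- rep(FALSE, nrow(out))
    if (nrow(out) == 0) warning("all records excluded; no deaths remain")
  } else {
    out <- records
    out$censored <- non_death
  }
  attr(out, "excluded_counts") <- excluded
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' From-formula product-limit estimator of the survival function of adult
#' lifespan: at each distinct event day \eqn{t_j} with \eqn{d_j} deaths among
#' \eqn{r_j} worms at risk, survival multiplies by \eqn{1 - d_j / r_j}.
#' Censored worms leave the risk set after their last observed day without
#' contributing a death. With no censoring the estimate equals the empirical
#' survival function, and the mean (area under the curve) equals the
#' arithmetic mean of the death days.
#'
#' @param death_days Numeric vector of event days (from adulthood).
#' @param censored Logical vector; `TRUE` marks a censored observation.
#' @return A `survival_curve`: list with `event_times`, `at_risk`, `deaths`,
#'   `survival`, `median_day`, `mean_day`, `n`.
#' @examples
#' km <- km_estimate(c(2, 4))
#' km$survival   # 0.5, 0
#' km$mean_day   # 3
#' @export
km_estimate <- function(death_days, censored = rep(FALSE, length(death_days))) {
  stopifnot(length(censored) == length(death_days))
  if (length(death_days) == 0 || all(censored)) {
    stop("at least one death is required for the product-limit estimate")
  }
  if (any(death_days < 0)) stop("event days must be >= 0")
  times <- sort(unique(death_days[!censored]))
  n <- length(death_days)
  at_risk <- vapply(times, function(t) sum(death_days >= t), numeric(1))
  deaths <- vapply(times, function(t) sum(death_days == t & !censored),
                   numeric(1))
  survival <- cumprod(1 - deaths / at_risk)
  # mean = area under the step curve from 0 to the last event time
  widths <- diff(c(0, times))
  mean_day <- sum(widths * c(1, survival[-length(survival)]))
  median_day <- if (any(survival <= 0.5)) times[which(survival <= 0.5)[1]]
                else NA_real_
  structure(list(event_times = times, at_risk = at_risk, deaths = deaths,
                 survival = survival, median_day = median_day,
                 mean_day = mean_day, n = n),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve> n = %d, mean %.2f d, median %s d, %d event times\n",
              x$n, x$mean_day,
              if (is.na(x$median_day)) "NA" else format(x$median_day),
              length(x$event_times)))
  invisible(x)
}

# O(k) two-group log-rank work-horse on pooled event data; returns the
# chi-square statistic (1 df). Exposed internally so the permutation oracle
# in the test suite can call it many times cheaply.
logrank_chi2 <- function(days_a, days_b) {
  all_days <- c(days_a, days_b)
  grp_a <- c(rep(TRUE, length(days_a)), rep(FALSE, length(days_b)))
  times <- sort(unique(all_days))
  obs_a <- 0
  exp_a <- 0
  var_a <- 0
  for (t in times) {
    at_risk <- all_days >= t
    n_t <- sum(at_risk)
    n_a <- sum(at_risk & grp_a)
    d_t <- sum(all_days == t)
    d_a <- sum(all_days == t & grp_a)
    obs_a <- obs_a + d_a
    exp_a <- exp_a + d_t * n_a / n_t
    if (n_t > 1) {
      var_a <- var_a + d_t * (n_a / n_t) * (1 - n_a / n_t) *
        (n_t - d_t) / (n_t - 1)
    }
  }
  if (var_a == 0) return(0)
  (obs_a - exp_a)^2 / var_a
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square test (1 df) comparing the death-time
#' distributions of two groups, implemented from the risk-table formulas,
#' together with per-group product-limit means/medians and the percent
#' change in mean lifespan of group A relative to group B.
#'
#' @param group_a_days,group_b_days Numeric vectors of death days.
#' @param labels Character vector of length 2 naming the groups.
#' @return A `lifespan_comparison`: list with `labels`, `mean_day`,
#'   `median_day`, `n`, `logrank_chi2`, `p_value`, `percent_change`.
#' @examples
#' logrank_test(c(18, 20, 22, 25), c(12, 14, 15, 16))
#' @export
logrank_test <- function(group_a_days, group_b_days,
                         labels = c("A", "B")) {
  if (length(group_a_days) == 0 || length(group_b_days) == 0) {
    stop("both groups must be non-empty")
  }
  chi2 <- logrank_chi2(group_a_days, group_b_days)
  km_a <- km_estimate(group_a_days)
  km_b <- km_estimate(group_b_days)
  structure(list(labels = labels,
                 mean_day = c(km_a$mean_day, km_b$mean_day),
                 median_day = c(km_a$median_day, km_b$median_day),
                 n = c(km_a$n, km_b$n),
                 logrank_chi2 = chi2,
                 p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 percent_change = percent_change(km_a$mean_day, km_b$mean_day)),
            class = "lifespan_comparison")
}

#' @export
print.lifespan_comparison <- function(x, ...) {
  cat(sprintf("<lifespan_comparison> %s: mean %.2f d vs %s: mean %.2f d (%+.1f%%), log-rank chi2 = %.2f, p = %.3g\n",
              x$labels[1], x$mean_day[1], x$labels[2], x$mean_day[2],
              x$percent_change, x$logrank_chi2, x$p_value))
  invisible(x)
}

#' Percent change of a mean relative to a reference
#'
#' `100 * (mean_a - mean_b) / mean_b`: positive when group A outlives the
#' reference group B.
#'
#' @param mean_a,mean_b Mean lifespans in days; `mean_b` is the reference.
#' @return Percent.
#' @examples
#' percent_change(13, 10) # +30
#' @export
percent_change <- function(mean_a, mean_b) {
  if (!is.finite(mean_b) || mean_b <= 0) stop("reference mean must be > 0")
  100 * (mean_a - mean_b) / mean_b
}

#' All-pairs log-rank comparisons
#'
#' Pairwise log-rank tests over a set of lifespan groups with a Bonferroni
#' column, the layout used for density-ladder lifespan tables.
#'
#' @param groups Named list of numeric death-day vectors.
#' @return `data.frame` with one row per unordered pair: group names, means,
#'   chi-square, raw and Bonferroni-adjusted p-values.
#' @export
pairwise_logrank <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2, !is.null(names(groups)))
  pairs <- utils::combn(names(groups), 2)
  rows <- apply(pairs, 2, function(pr) {
    cmp <- logrank_test(groups[[pr[1]]], groups[[pr[2]]], labels = pr)
    data.frame(group_a = pr[1], group_b = pr[2],
               mean_a = cmp$mean_day[1], mean_b = cmp$mean_day[2],
               chi2 = cmp$logrank_chi2, p = cmp$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni_adjust(out$p)
  out
}
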