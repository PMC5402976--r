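---
title: "The pddasim model: density-dependent development and lifespan in C. elegans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pddasim model: density-dependent development and lifespan in C. elegans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pddasim)
```

## The phenotype and its metric

*C. elegans* hermaphrodites reared at high density (HD, 50--100 worms per
plate) reach reproductive maturity -- operationalized as the time the first
egg is laid -- a few hours earlier than worms reared in isolation (ISO, one
worm per plate). This population density-dependent acceleration of
development (Pdda) is quantified by the difference of arm means of the time
to first egg laying, normalized to the effect in the parallel wildtype
experiment and to the strain's own absolute developmental time:

$$\mathrm{Pdda}\,[\%] =
  \frac{t_{ISO}^{mut} - t_{HD}^{mut}}{t_{ISO}^{wt} - t_{HD}^{wt}}
  \cdot \frac{t_{ISO}^{wt}}{t_{ISO}^{mut}} \cdot 100$$

The second factor removes strain-wide rescaling of developmental speed:
in the generative model a strain whose only difference from wildtype is a
reduced feeding rate (the `feeding_rate_factor` of a genotype profile, as in
*eat-2*) has both its time difference and its ISO time inflated by the same
factor, so the metric stays at exactly 100%. `pdda_percent()` implements the
formula verbatim; `iso_hd_contrast()` carries the propagated uncertainty
$\sqrt{s^2_{ISO}/N_{ISO} + s^2_{HD}/N_{HD}}$ (algebraically the standard
error of the difference of two independent means, and reported as such) and
a Welch two-sample test computed from the arm summaries. Multi-replicate
Pdda is the unweighted mean of per-replicate values; weighting replicates by
worm count is a defensible alternative, but with balanced designs the two
coincide and equal weighting matches how replicate averages are usually
reported.

## The push-pull generative model

The simulator emulates the study's explanatory model: two excreted
small-molecule signals accumulate on a plate in proportion to occupancy
(worms x hours, `signal_level()`), an unidentified compound that
*accelerates* development (called X here) and ascaroside pheromones that
*decelerate* it. A worm singled at the transfer time $t^* = 59$ h has
experienced exposures $X$ and $A$, frozen at $t^*$, and matures at

$$T = \frac{T_0}{f}\Big(
  1 + \delta_A\, g_A\, \mathrm{sat}(A, K_A)
    - \delta_X\, g_X\, \frac{\mathrm{sat}(X, K_X)}{1 + g_I g_A A / K_I}
  \Big) + \varepsilon,
  \qquad \mathrm{sat}(u, K) = \frac{u}{u + K},$$

with $\varepsilon \sim N(0, \sigma^2)$ truncated at $\pm 4\sigma$ and
genotype-specific $T_0$, $f$ and $\sigma$. Design choices that deserve
justification:

* **Ascarosides act twice.** A small additive delay ($\delta_A$) and a
  multiplicative inhibition of the X response ($K_I$). The inhibition term
  is what lets the model reproduce two facts simultaneously: wildtype Pdda
  (2--5 h) is far below that of ascaroside-free mutants (8--17 h), and
  adding synthetic ascarosides *to both arms equally* suppresses Pdda. A
  purely additive braking term cannot do the latter: with a concave
  dose-response, equal-arm supplementation always shrinks the braking
  *difference* between arms and would widen the gap instead.
* **The X response is weakly saturating** ($K_X = 10^5$ units, effectively
  linear across assay densities). Together with the inhibition term this
  keeps the deterministic maturation time monotone non-increasing in plate
  occupancy throughout the per-worm assay range (verified for 1--150 worms
  per plate; the braking term overtakes only near ~290 worms per plate,
  beyond any condition in which per-worm times are measured), and monotone
  non-decreasing in exogenous ascaroside dose.
* **Epistasis is a gain table, not a mechanism.** `effective_gains()` maps
  pathway flags to $(g_X, g_A, g_I)$: cilium-defective strains have
  $g_A = 0$ (and hence no ascaroside input at all); insulin-pathway loss in
  either direction, or receptor-saturating dafachronic acid (DA) on a
  DAF-12(+) background, silences $g_X$; *nhr-8* loss silences it but DA
  restores it; joint *nhr-8;daf-12* loss enhances $g_X$ (to 1.0404, fixed
  once so the double mutant's deterministic gap equals that of the
  ascaroside-free strain) and sets $g_I = 0$, making the strain blind to
  both DA and ascaroside feedback. The underlying receptor biochemistry is
  unresolved in the field; the table is deliberately phenomenological.
  Undeclared flag combinations (e.g. DA-biosynthesis loss with intact
  DAF-12 and no rescue) fall back to wildtype gains with a warning.
* **Perception of X is cilium-independent.** Cilium-defective strains show
  the enhanced, not an abolished, phenotype, so the accelerating signal
  bypasses $g_A$ entirely. Whether the real compound is perceived
  internally or by another sensory route is an open question; the model
  simply does not couple it to the chemosensory flags.
* **Exposure is frozen at transfer.** Worms are singled onto fresh plates
  at 59 h; a lone worm deposits too little before egg laying begins to
  matter, so the singled phase contributes no further signal.

Calibration constants live in `inst/extdata/calibration.yaml` and were fixed
once, by solving the deterministic core against the published effect sizes
(wildtype gap ~3.1 h inside the 2--5 h band, ascaroside-free gap 12.3 h
inside 8--17 h, staging lead ~2.5 h inside 2--3 h), before any stochastic
testing. Baseline maturation times put strains with strongly enhanced
density responses at $T_0 = 76$ h so that even their fastest HD worms lay
after scoring begins; this matches the strong ISO delay such strains show.

Scoring discretizes maturation times by ceiling to the next whole hour, never
before the 60 h scoring start (`score_first_egg()`); embryonic survival is
97% and unhatched worms are flagged and excluded from summaries.

### Pre-conditioned plates

`simulate_preconditioned_assay()` models plates previously occupied by
100--150 worms until their removal at L4 (~45 h): isolated worms then start
with `carryover` (0.93) of the deposited signal already present -- and
deposited ascarosides only if the conditioning strain makes them. One
exposure setting reproduces both qualitative observations: conditioned
isolated ascaroside-free worms sit strictly between their ISO and HD arms,
and conditioned *nhr-8;daf-12* worms come within ~0.8 h of their HD arm.

### Staging

At the 52 h staging observation each worm's position on the ordinal stage
scale (L1, L2, L3, L4.1--L4.9, YA, Adult) is obtained by mapping it onto a
reference timeline: a worm maturing in $T_i$ hours is, at clock time $t$, as
far along as a reference worm at $t \cdot T_{ref}/T_i$. The stage-time map
anchors L4.2 at 52 h and L4.5 at 57 h on the isolated-wildtype timeline and
interpolates L4 sub-stages linearly (5/3 h each); `developmental_lead_h()`
inverts the same map, so the recovered lead is unbiased up to
discretization, which the between-worm noise dithers away. Stage
distributions are compared by a midrank Wilcoxon rank-sum test on the
ordinal scale (the original report shows significance stars without naming
the test; a rank test is the standard choice for ordered categories and its
null uniformity is property-tested).

## Lifespan

Adult lifespan (days from young adulthood) follows a Gompertz law with
hazard $a e^{bt}$, $b = 0.3\,\mathrm{d}^{-1}$ (giving a realistic ~4 d
lifespan SD). The baseline $a$ rises with *larval* crowding through a
saturating function of density, and -- only at low larval density -- with DA
exposure (amplitude decaying as $e^{-(d-1)/3}$ so that 20 or more worms per
plate behave like mock). Adult density never enters the death-time
distribution: under protocol I (worms distributed onto assay plates as
young adults after high-density rearing) all assay densities share one
larval history and hence one lifespan distribution, whereas protocol II
(assay density from the egg onward) produces the ~4.6 d advantage of
lifelong isolation over groups of 50 and the ~29% advantage over
protocol I at one worm per plate. These anchors were calibrated numerically
(against the day-resolution scoring, i.e. after the ceiling to whole days)
and frozen.

Worms lost to internal hatching, vulval rupture, or leaving the plate
(calibrated rates 3/2/3%) are *excluded*, not censored, by default
(`apply_exclusions()`), matching assay practice; a censoring mode exists for
users who prefer it. `km_estimate()` and `logrank_test()` are implemented
from the product-limit and risk-table formulas -- the survival analysis is
part of the package's subject matter, not a convenience dependency -- and
are cross-checked in the test suite against an independent implementation
(`survival::survfit`/`survdiff`) and against label-permutation oracles. Mean
lifespan is the area under the survival curve, which equals the arithmetic
mean of death days in the uncensored case; day counting starts at the
young-adult transfer, so protocol I and II are aligned on the same clock.

## Protocol A and the order-statistic confound

Scoring a whole plate for its first egg records the *minimum* of n per-worm
times, so apparent onset drops with plate size even for identical worms.
`plate_first_event_time()` quantifies this confound by Monte-Carlo; it is
the reason the per-worm transfer protocol exists, and the package treats
plate-level scoring only through this lens.

## Numerical and testing choices

* All simulators take an explicit seed; identical seeds give byte-identical
  output, and the caller's RNG state is restored. Multi-arm runs derive
  child seeds (kept below $2^{31}$) from one master seed.
* Welch tests are computed from arm summaries (mean, SD, N) via
  Welch--Satterthwaite; this equals `t.test()` on the raw data and keeps the
  contrast operation well-defined on published summary tables. A
  single-worm arm contributes zero variance, with a warning.
* The test suite checks oracle equivalences at desk scale: bootstrap SEs
  (10,000 reps), studentized permutation p-values (20,000 reps), null
  type-I rates (6,000 simulations, keeping the Monte-Carlo error of the
  rate estimate well inside the tested 0.05 +/- 0.01 band), and a KS check
  of null p-value uniformity for the staging test (1,000 simulations).
  Simulated recovery of the published effect sizes uses 100 worms per arm
  (60 for staging) averaged over 10 seeds.

## What the simulator does and does not claim

Passing tests show that the analysis pipeline is correct on data whose
generative structure embodies the push-pull model: Gaussian maturation
noise, linear signal deposition, saturating dose-responses, Gompertz
mortality, and exclusion-type losses. Real assays add plate-level batch
effects, non-Gaussian and possibly skewed maturation noise, bacterial lawn
heterogeneity, temperature drift and observer effects, none of which are
modeled; the spread of the unidentified accelerating signal between the two
published bands (wildtype 2--5 h vs ascaroside-free 8--17 h) is also not
separable from the published data, so the calibration resolves that split
by one choice among many compatible ones. Conclusions about real data
should rest on the statistical modules (which ingest plain CSV via
`read_worm_observations()` / `read_lifespan_records()`), not on the
calibration.
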