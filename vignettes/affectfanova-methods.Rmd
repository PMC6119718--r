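---
title: "Testing individual differences in continuous emotion ratings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing individual differences in continuous emotion ratings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(affectfanova)
```

## The problem

In continuous emotion-rating experiments, listeners move a cursor through a
two-dimensional emotion space (valence on the horizontal axis, arousal on
the vertical) while a music excerpt or speech sample plays. Sampled at
1 Hz and normalized to $[-1, 1]$, each listener yields one rating *curve*
per stimulus and dimension. The scientific question this package addresses
is whether groups of listeners defined by stable individual differences —
Big-Five personality mean splits, trait emotional intelligence, gender,
extensive musical training, age over 40 — produce different *mean rating
curves*, moment by moment, rather than different summary judgments.

Curves observed at 45–156 grid points on ~50 participants are functional
data: the number of grid points exceeds the number of raters, so pointwise
or multivariate ANOVA is ill-posed, and the quantity of interest is the
whole mean function. The package implements the full pipeline: data model
and I/O, preprocessing and reliability screening, covariate scoring and
dichotomization, a functional ANOVA with bootstrap calibration, a
multiplicity-corrected test battery, and a synthetic-study generator that
reproduces the statistical structure the analysis assumes.

## The test

For groups $a, b$ with $n_a, n_b$ curves on a common grid, each curve is
smoothed by local polynomial regression (local linear by default) and the
group mean functions $\hat m_a, \hat m_b$ are the averages of the smoothed
curves. The test statistic is of Cramér–von Mises type,

$$C = \frac{n_a n_b}{n_a + n_b} \int_T \left(\hat m_a(t) - \hat m_b(t)\right)^2 dt,$$

with the integral taken by the trapezoid rule on the 1 Hz grid (grids are
never interpolated to a finer mesh). With $k > 2$ groups the statistic is
the sum of the pairwise terms; all nine factors here are dichotomous, so
the two-group form is the operative one. `cvm_statistic()` computes this;
for noiseless curves differing by a constant $\delta$ with equal group
sizes $n$ it equals $(n/2)\,\delta^2\,(T_{end}-T_{start})$ exactly, which
the test suite uses as a closed-form oracle.

### Bootstrap calibration

The null distribution of $C$ is approximated by a functional bootstrap on
whole curves. Residual curves are formed as each raw curve minus its own
group's smoothed mean; `B` times, residual curves are drawn with
replacement *within each group*, re-smoothed at the originally selected
bandwidth, averaged per group, and the statistic $C^*$ recomputed. The
p-value is $(1 + \#\{C^* \ge C\})/(B+1)$, so p-values live on the grid
$k/(B+1)$ with minimum $1/(B+1)$. Resampling whole curves preserves each
curve's autocorrelation; resampling within groups preserves group-specific
dispersion, which is what makes the test valid under heteroscedasticity
(groups with unequal rating noise).

Two finite-sample details matter for calibration and are part of the
implementation:

* **Residual re-centering.** The smoothed group mean is not the raw group
  mean, so raw-minus-smoothed-mean residuals retain the rough component of
  the group mean as a *common* offset. Left in place, that offset adds the
  same noncentrality to every bootstrap replicate and inflates the whole
  $C^*$ distribution. Residuals are therefore re-centered within group.
* **Variance rescaling.** Centered residuals underestimate dispersion by
  the usual factor $(n-1)/n$; they are rescaled by $\sqrt{n/(n-1)}$, the
  standard residual-bootstrap correction.

Because the smoother is linear, re-smoothing resampled residuals equals
resampling pre-smoothed residual columns; the implementation precomputes
the smoothed, centered, rescaled residual matrix once per test, which is
what makes 500-replication calibration studies cheap.

## Smoothing and bandwidth

`smoothing_spec()` controls the local polynomial fit: degree 1 by default
(exact on linear trends, well-behaved at curve ends), Epanechnikov kernel,
bandwidth in seconds. Degree-0 (kernel average) and degree-2 fits are
available; a bandwidth below the grid step, or one leaving fewer active
points than coefficients at some grid point, is an error rather than a
silent extrapolation.

Bandwidth selection (`select_bandwidth()`) is cross-validation with two
deliberate departures from the textbook recipe, both consequences of the
data being serially correlated curves rather than independent scatter:

* **Leave-block-out, not leave-one-out.** Rating noise is autocorrelated
  over a few seconds (the generator's default AR(1) coefficient is 0.5).
  Plain LOO lets the immediate neighbours "predict" the held-out noise and
  drives the bandwidth toward the grid step; the resulting near-zero
  smoothing leaves a high-dimensional residual space whose sample
  covariance has badly inflated top eigenvalues, and the bootstrap test
  then runs visibly conservative. The fix is standard: the fit predicting
  second $t$ omits all observations within `block` seconds of $t$
  (default 3 s; `block = 0` recovers LOO exactly).
* **A capped candidate grid.** Candidates are log-spaced from 1.5 grid
  steps to one-eighth of the observation window. The cap is a modelling
  statement, not a numerical convenience: on stretches where the mean is
  featureless the CV criterion keeps improving with $h$ indefinitely, so
  *some* cap is always the operative choice, and smoothing beyond ~$T/8$
  visibly flattens the localized, seconds-scale group differences the
  design predicts individual differences should produce. Bandwidths
  optimal for estimating a single curve are not optimal for testing mean
  differences; mild undersmoothing costs variance that the bootstrap
  calibration absorbs, while oversmoothing costs bias that nothing
  recovers.

Each curve votes for its CV-optimal candidate (ties toward the smallest);
the lower median of the per-curve optima is shared by all curves of one
stimulus × dimension so that group means are comparable.

```{r bandwidth}
tt <- 0:119
curves <- simulate_rating_curves(26, tt, 0.5 * sin(tt / 15),
                                 rho = 0.5, sigma = 0.15, seed = 1)
select_bandwidth(curves, tt)
```

## Preprocessing and reliability screening

Raw device coordinates are mapped affinely onto $[-1, 1]$
(`normalize_ratings()`), missing seconds are filled by
last-observation-carried-forward from a neutral start (the cursor position
persists between movements; `fill_rating_gaps()`), and the per-second value
is taken to represent the second $[t, t+1)$ — the alignment is a
convention, stated rather than estimated.

Panel reliability per stimulus × dimension is Cronbach's alpha computed on
the individual time series with participants as items and seconds as cases
(`cronbach_alpha()`), i.e.
$\alpha = \frac{k}{k-1}\bigl(1 - \sum_i \mathrm{Var}(x_i) / \mathrm{Var}(\sum_i x_i)\bigr)$
with sample variances. Alpha is scale- and shift-invariant, so whether raw
or normalized series are used is immaterial. Negative values (raters
moving in opposition) are reported as-is, never clamped. Cells with
$\alpha$ below the retention threshold are screened out of testing but stay
in the battery enumeration. The default threshold is 0.75: in the
published 17-stimulus reliability table this package models its screening
on, 0.75 retains the borderline 0.78 cell and drops 0.73, 0.65 and 0.15,
reproducing that study's keep/drop set; the threshold is an explicit
argument, not a constant. One printed value in that source is ambiguous
(reported as −0.73 in the text but 0.73 in the table); the package always
reports the computed value and leaves interpretation to the analyst.

## Covariates and grouping factors

TIPI Big-Five scores are the mean of one direct and one reverse-keyed item
per dimension (reverse-keying as $8 - x$); trait emotional intelligence is
the mean of 30 keyed items. The instruments' published reverse-key lists
ship as defaults (`tipi_key()`, `teique_reverse_key()`) and are arguments
because printed forms vary. Mood is scored as the mean of three valence
and three arousal semantic-differential items in $-3..3$, with pre/post
difference scores available; the package deliberately stops at difference
scores (their omnibus MANOVA is a stock analysis, not part of this
pipeline).

Trait factors dichotomize at the sample mean by the sign of the z-score;
a score exactly at the mean goes to the low group — an arbitrary but
deterministic and configurable tie rule. Mean splits are invariant under
positive affine transforms of the scores. Musical training contrasts
≥10 years against <1 year, excluding the middle band from that factor
only; age splits strictly above 40; gender is taken as recorded. Nine
factors result, and each partitions the retained participants (minus any
factor-specific exclusions) into exactly two levels.

## The battery and multiplicity

`run_battery()` crosses every stimulus with both dimensions and all nine
factors — 306 tests for the full 8-music + 9-speech design — skipping
reliability-excluded cells at execution while keeping them enumerated.
Each test's bootstrap seed is derived deterministically from the master
seed and the test's ordinal index, so results are independent of execution
order and bit-reproducible. Individual test failures are recorded and the
battery continues; more than 10% failures aborts.

BH correction needs a family definition, and the design offers three
readings. The default, `per_factor`, adjusts across the stimuli of one
modality for a given dimension × factor — families of 8 (music) or 9
(speech), matching the design's stated family size of 8 per correction.
`per_stimulus` (all 18 tests of one stimulus) and `global` are available,
with one hard constraint worth knowing: the smallest attainable raw
p-value is $1/(B+1)$, so a family of $m$ tests can only ever reject at
level $q$ when $m/(B+1) \le q$ — at $B = 199$ and $q = 0.05$ an 18-test
family can never reject anything. When ranking cells across the battery
(e.g. asking whether an injected effect is the top hit), the raw p-value
is the right ordering: adjusted values are family-relative and not
comparable between families.

## The synthetic-study generator

`simulate_study()` generates the complete data object the pipeline
consumes, so every stage is testable without any external download. Its
defaults *are* the emulated study conditions:

* 60 recruited participants, of whom 2 carry measurement-error flags and 6
  non-native-speaker flags, leaving the 52-participant analysis sample
  (26 female / 26 male; training bands 15 / 20 / 17; ages truncated-normal
  around 32, SD 13, within 18–62).
* 8 music + 9 speech stimuli, 45–156 s at 1 Hz, each with a mean
  valence/arousal trajectory built as a natural cubic spline through
  waypoints visiting the stimulus's expected emotion-space quadrants
  (`make_mean_function()`, `default_waypoints()`).
* Participant effects: multiplicative amplitude
  $a_i \sim \mathrm{LogNormal}(0, 0.15^2)$ and additive offset
  $b_i \sim N(0, 0.1^2)$, emulating raters who use the scale more or less
  expansively and anchor it differently.
* Rating noise: stationary AR(1) with $\rho = 0.5$ and innovation SD
  $\sigma = 0.15$, optionally group-specific (`sigma_by_level`) to produce
  the heteroscedastic regime the test claims to handle. A participant's
  curve is $\mathrm{clip}(a_i \mu(t) + b_i + e(t))$, clipped to $[-1,1]$
  after noise, accepting mild boundary censoring as in real bounded-slider
  data.
* Group effects are localized Gaussian bumps
  $A \exp(-(t-t_0)^2 / 2w^2)$ added to the affected level's mean function
  (`inject_group_effect()`) — individual differences are expected to
  matter most during specific regions of a stimulus, and this is that
  shape. Injected effects are recorded in a truth manifest for recovery
  studies.

The noise magnitudes are the package's own choices — the emulated study
reports no participant-level noise parameters — fixed once to place panel
reliability in the observed regime (mostly high alphas, degrading toward
useless as $\sigma$ grows; the suite checks monotonicity). Questionnaire
items are back-filled from latent trait draws so that scoring the items
approximately recovers the latent scores, keeping covariate scoring
round-trippable. What the generator does **not** model: mouse kinematics
and reaction lag, acoustic features of the stimuli, rater drift, or
mixed/ambivalent emotion. Passing tests therefore demonstrate the
pipeline's statistical behaviour under its stated assumptions, not
fidelity to any particular real dataset.

## Calibration evidence and problem sizes

The test suite re-derives, at fixed seeds, the quantities that justify the
implementation (sizes chosen to keep the full suite around three minutes):

* **Size.** 500 null replications (two groups of 26 curves, $T = 120$,
  $\rho = 0.5$, $\sigma = 0.15$, $B = 199$): the rejection rate at the
  0.05 threshold must fall in the binomial 95% interval around 0.05; under
  heteroscedasticity ($\sigma = 0.1$ vs $0.4$) within $[0.03, 0.08]$.
  `scripts/acceptance.R` recomputes the homoscedastic rate from scratch
  for any seed.
* **Power and recovery.** Twenty replicate studies (4 stimuli to bound
  runtime; the test's n, noise and bootstrap size as above) with one
  injected gender bump ($A = 0.3$, $w = 10$ s) on one stimulus's valence:
  the affected cell must be BH-significant in ≥80% of replicates and the
  battery's smallest raw p in ≥80%. The residual misses are instructive
  rather than worrying: the bump genuinely leaks into other dichotomies of
  the same 52 participants that chance-correlate with gender, and with 71
  null tests an occasional null cell hits the $1/200$ p-value floor.
* **Oracles.** Cronbach's alpha against the two-way ANOVA decomposition,
  BH against the brute-force largest-$k$ rule and `stats::p.adjust`, the
  CvM statistic against its closed form, local-linear smoothing against
  exact linear reproduction.

## Known limitations

* The bootstrap is the only calibration offered; no asymptotic/χ²
  approximation is implemented, so p-value resolution is $1/(B+1)$ and
  computing cost scales with $B$.
* Whole-curve tests only: a significant cell says the mean functions
  differ somewhere, and the package deliberately offers no interval-wise
  localization of where.
* Mean-split dichotomization discards predictor variance; it is kept
  because it is the design being modelled, not because it is efficient.
* With ~26 curves per group the bootstrap covariance is estimated from few
  functional observations; the re-centering and rescaling above remove the
  first-order biases, but mild conservatism can remain at minimal
  smoothing.
* The generator's trait covariates are independent draws; real Big-Five
  and EI scores correlate, so battery-level false-positive clustering
  across factors may differ on real data.
* Participant amplitude and offset effects persist across stimuli (as they
  do for real raters), so for a given factor the battery's tests are
  positively dependent across cells: a roster whose realized group gap in
  offsets happens to be large produces same-direction rejections on many
  stimuli at once, rather than independent scattered ones. Per-test size
  is unaffected; the clustering of rejections is.
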