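---
title: "Methods: BCT gestational weight gain charts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BCT gestational weight gain charts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`gwgchart` estimates the conditional distribution of gestational weight
gain given gestational age, separately per pre-pregnancy WHO BMI group,
with the Box-Cox *t* (BCT) distribution. Writing `y = gain + 20` kg for
the shifted gain and `t` for gestational age in decimal weeks, the model
assumes

```
z = ((y / mu(t))^nu(t) - 1) / (nu(t) * sigma(t))   (nu != 0; log branch at nu = 0)
z ~ Student t with tau(t) degrees of freedom,
```

so `mu(t)` is the median of `y`, `sigma(t)` an approximate coefficient of
variation, `nu(t)` a skewness power, and `tau(t)` a kurtosis parameter.
For `nu != 0` the Box-Cox map bounds `z` on one side; the cdf is
renormalized by the *t* mass of the feasible range so the distribution is
proper on `y > 0`. At fitted chart parameters this correction is of order
1e-10, but it is carried exactly in `bct_cdf()` / `bct_quantile()` /
`bct_pdf()`; the fitting derivatives ignore it, the standard GAMLSS
treatment. `|nu| < 1e-6` routes to the log branch to avoid cancellation.

Two modelling assumptions are adopted deliberately. First, the data are
modelled cross-sectionally: repeated observations of one woman enter as
independent, because accounting for the within-woman correlation has a
negligible effect on the location and precision of centiles while greatly
complicating the fit. Second, the reference is descriptive: all women with
a classifiable pre-pregnancy BMI enter the main fit; the uncomplicated
subset (no hypertensive or diabetic disorder, term delivery,
appropriate-for-gestational-age infant) is a separate restriction
(`filter_uncomplicated()`), with unknown flags excluding a woman from the
subset but never from the full fit.

## Preprocessing

* **Week-0 anchor.** Every woman contributes an implied week-0
  observation, weight equal to her pre-pregnancy weight, hence a gain of
  exactly 0 kg. A point mass breaks the likelihood, so each week-0 gain is
  replaced by a draw from Normal(0, 0.98 kg²): a gain is a difference of
  two weighings, each with a dial measurement error of about 0.70 kg, so
  its error variance is 0.70² + 0.70² = 0.98 kg². Only week-0 rows are
  nudged; the draw is seeded and the seed stored in the fit metadata.
* **Positivity offset.** The BCT lives on positive values and gains may be
  negative, so the model is fit on `y = gain + 20` (−20 kg being an
  extremely low weight change). Rows with `y <= 0` after nudging are
  dropped and counted; the threshold is on post-nudge `y`, matching the
  order in which the transformations are defined.
* **Windows.** At most one weight per pregnancy window is used: the
  observation closest to 13 weeks within 6-19.9, to 26 within 20-31.9,
  and to 40 within 32-45. Distance ties break to the earlier observation
  (a deterministic rule; any fixed rule would do). BMI group boundaries
  are half-open `[lower, upper)` so every positive BMI is classifiable.

## Parameter curves, links, and smoothing

`mu` uses an identity link and a degree-3 regression B-spline with
internal breakpoints {12, 20, 28, 34} weeks and boundary knots at 0 and
45 — enough flexibility for the slow first half, the mid-pregnancy rate
change around 22-25 weeks, and the near-linear run to term. `sigma` and
`tau` use log links (positivity by construction), `nu` an identity link.
Their curves are penalized cubic B-splines on equally spaced knots with a
second-order difference penalty, with effective df 3 (S) and 2 (L, T) by
default: the S-shape of the variation curve needs one bend; skewness and
kurtosis are kept near-linear to avoid chasing noise in the tails. The
penalty's null space on equally spaced knots is exactly the affine
functions, so df = 2 is a straight line on the link scale. The smoothing
parameter of each curve is solved at fit time so the trace of its
smoother matrix equals the requested df; smoothing is fixed by df rather
than estimated, and model selection is manual via the diagnostics, the
worm plots and Q statistics serving as the arbiters. Per-group overrides
go through `model_spec()`.

## Fitting algorithm

`fit_gamlss_bct()` maximizes the penalized BCT log-likelihood by cyclic
Rigby-Stasinopoulos backfitting: for each parameter in turn (mu, sigma,
nu, tau), form the working response `eta + u/w` from the analytic score
`u` on the link scale, with weights `w` the observed information obtained
by central differencing of the score (clamped to [1e-4, 1e6]), and solve
a penalized weighted least-squares problem, holding the other curves
fixed. Numerical choices that matter:

* **Initialization.** `mu` starts at a B-spline fit through weekly
  running medians; `sigma` at the robust coefficient of variation
  (MAD/median) of `y`, the classic LMS-style warm start — a much smaller
  start makes the initial |z| values saturate the *t* score and stalls
  the first cycles; `nu` at 1; `tau` at 10.
* **Step-halving.** Each parameter update is accepted only if the fitting
  criterion (deviance + roughness penalties) does not increase; otherwise the step is halved, a bounded number of times. This enforces the monotonicity
  that the tests assert per outer iteration.
* **Fixed objective.** The per-curve smoothing parameters are re-solved
  against the df targets during the first three cycles and then frozen,
  so later cycles minimize a fixed objective and monotonicity is
  well-defined.
* **Rank safety.** The penalized normal equations carry a ridge of
  1e-6 times the mean diagonal of B'WB (basis columns with little support
  in the 0-6 week gap) plus 1e-10 of the penalized matrix's own diagonal
  (scale mismatch at large smoothing). The ridge bounds how exactly the
  df = 2 limit reproduces an affine function (to about 1e-4 in practice).
* **Convergence.** Outer tolerance 1e-3 on the criterion, at most 50
  cycles; non-convergence returns the fit with `converged = FALSE` and a
  warning rather than an error.
* **Link-scale clamps.** `eta` values are clamped to generous domains
  (sigma in [1e-4, 5], tau in [0.2, 1e7], nu in [-10, 10], mu in
  [0.05, 200] kg) so a wild intermediate step cannot produce NaN
  likelihoods; the clamps are never active at a converged chart fit.

`BIC = deviance + log(n) * total effective df` is compared against an
ordinary least-squares linear baseline (3 parameters) via
`compare_bic()`; positive differences favor the chart.

## Chart deliverables

`export_parameter_grid()` evaluates the curves at integer weeks 0-42 (the
chart's visual range); the calculator accepts ages to 45 by linear
extrapolation from the terminal grid pair, with a warning. Parameters at
non-integer ages are linearly interpolated per parameter — interpolating
parameters rather than quantiles keeps `gain_to_zscore()` and
`centile_curve()` mutually consistent, and reproduces grid values exactly
at integer weeks. Both the t-scale `z_raw` (the Box-Cox z itself) and the
normal-equivalent `z_normal = qnorm(F_BCT(y))` are returned: percentile
labels (P2.3 = −2 SD, …) are only coherent on the normal-equivalent
scale, so that is the reported chart z-score, while the t-scale value is
exposed for completeness. Grids are stored at full precision; rounding is
display-only in the centile CSVs. IOM ranges (12.5-18, 11.5-16, 7-11.5,
5-9 kg; the obesity grades share 5-9) are treated as closed intervals,
boundary handling being unstated in the guidelines.

## Diagnostics

Worm plots use equal-count GA bins (week-0 rows form their own bin when
they exceed 10% of the data — they are a point mass in age), Blom
order-statistic medians, and the pointwise band
`1.96*sqrt(p(1-p)/n)/dnorm(q)`. Q statistics screen the first four
moments of the normal-equivalent residuals per GA group: the mean via
`m*sqrt(n)`, the variance via the Wilson-Hilferty cube-root chi-square
standardization, skewness and kurtosis via the D'Agostino and
Anscombe-Glynn normal deviates; each moment's sum of squares is referred
to chi-square with `n_groups` minus the corresponding curve's effective
df (mean ↔ M, variance ↔ S, skewness ↔ L, kurtosis ↔ T), floored at 1.
The subgroup-consistency screen compares fitted median curves across
subgroups as a per-week variance in kg², judged against the 0.98 kg²
measurement-error variance — a stated, testable surrogate for a
coefficient-of-variation comparison whose exact form is not pinned down.

## The synthetic generator

`simulate_cohort()` emulates what the analysis assumes: six BMI groups
(BMI uniform per group, underweight floored at 15 and obesity grade 3
capped at 50 kg/m²; height Normal(1.65, 0.07) truncated to 1.40-1.95 m),
per-window observation ages, a median-gain truth curve per group — a
shape-preserving cubic Hermite through (0, 0) and published medians at 20
and 40 weeks, with the week-0 derivative set to half the first secant to
give the early-pregnancy lag — constant truth sigma = 0.06, nu = 0.8,
tau = 12 (invented, realistic constants, config-exposed; recovery tests
assert recovery of whatever truth is configured), 0.70 kg dial error, and
Bernoulli complication flags (8% hypertensive, 5% diabetic, 6% preterm,
20% SGA/LGA — conventional prevalences). Each woman's gains across
windows share one uniform, so margins are exactly BCT while trajectories
track within woman; week-0 and early-pregnancy weights correlate above
0.95 as in real cohorts.

What the generator does *not* emulate, and what that means for the tests:
measurement error is added *on top of* the BCT gain, so the observable
distribution is a BCT convolved with a Gaussian — not exactly a BCT. At
the default cohort sizes the median and coverage recovery are unaffected
(the tests pass at 0.3 kg and binomial tolerances), but the variance and
kurtosis Q statistics correctly reject at n ≈ 7000: the diagnostics are
doing their job on a model that is (mildly, by design) misspecified.
Passing recovery tests therefore demonstrate calibration of the location
and outer-centile machinery, not that real cohort data are exactly BCT.
Cohort heterogeneity, self-report provenance, and real BMI-group
prevalences are not modelled. `simulate_iom_mix()` realizes designed
adequacy proportions by stratified inverse-cdf sampling within the
category probability bands (exact counts, no rejection loop needed).

## Problem sizes

The reference recovery fit uses 5000 women (≈18,500 observations after
windowing), fixed seed; replicate recovery and subgroup screens use
700-2000 women per fit; Q-statistic null calibration uses 200 replicates
of 2000 residuals in 8 groups; the calculator contract is checked on
10,000 random (gain, age, group) triples. The six-group end-to-end run
uses 2000 women per group. These sizes were chosen to make Monte-Carlo
tolerances (0.3 kg on medians, binomial bands on coverage, the
[0.01, 0.12] rejection band) comfortably discriminating.

## Known limitations

* Exact per-group breakpoints and df of the published charts are not
  public; the defaults here are one sensible choice, and per-group
  overrides are configuration, not code.
* The fit treats observations as independent; standard errors implied by
  the information matrix would be optimistic for clustered data (they are
  not reported).
* `tau` is weakly identified at these sample sizes; its curve is kept at
  2 df and wide recovery tolerances for good reason.
* The calculator extrapolates linearly beyond week 42; beyond the data
  range any chart is an extrapolation and is warned about.
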