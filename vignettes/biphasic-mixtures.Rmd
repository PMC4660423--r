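---
title: "Two-dimensional Loewe additivity for biphasic dose-response curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-dimensional Loewe additivity for biphasic dose-response curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biphasicCI)
```

## The problem

Inducible whole-cell biosensors — for example cyanobacteria carrying a
metal-responsive promoter fused to a luciferase operon — respond to an
analyte with an inverted v-shaped ("biphasic") dose-response curve: the
signal (a bioluminescence induction factor, BIF) rises with dose up to a
maximum permissive concentration (MPC) and then declines as the analyte
becomes toxic to the cell.  Two features of such curves break the
classical machinery of mixture toxicology: different analytes reach
*different maximal effects*, and *two doses share each effect level*
(one on each branch).  Loewe additivity (concentration addition), the
standard null model for mixtures of similarly acting agents, is defined
through the scalar effective dose ED\_p and cannot be written down for
such curves without extension.

This package implements a two-dimensional extension.  The fractional
effect scale is decoupled from the empirical effect scale: a level
$p \in (-100, 100)$ indexes position along the curve, with $p < 0$ on
the induction branch, $p = 0$ at the peak, and $p > 0$ on the inhibition
branch.  The effective dose becomes a *vector*

$$ED_p = \big(D_{(p)},\, E_{(p)}\big),$$

the dose that produces fractional effect $p$ together with the empirical
effect attained there.  Loewe additivity is then formulated separately
in the dose ($D$) and effect ($E$) dimensions, and departures from it
are scored by a two-dimensional combination index.

## The curve model

Both model kinds share one split-peak form,

$$y(x) = c + (d - c)\exp\left(-\tfrac12\left(\frac{\Delta}{w}\right)^2\right),
\qquad
w = \begin{cases} b & \Delta \le 0\\ b\,f & \Delta > 0,\end{cases}$$

with $\Delta = x - e$ on the dose scale (`gaussian`) or
$\Delta = \ln x - \ln e$ on the log-dose scale (`loggaussian`).  The
parameters have direct readings: $c \ge 0$ is the baseline (the limit in
both tails), $d > c$ the peak response $E_{max}$, $e$ the peak location
(the MPC), $b > 0$ the width of the ascending branch, and $f > 0$ the
asymmetry — the descending branch is $f$ times as wide, $f = 1$ giving a
symmetric peak.  A log-dose model is the natural default for
concentration data spanning serial dilutions; model kind is otherwise an
empirical choice made by residual sum of squares (`select_model()`).

The fractional-effect mapping interpolates between baseline and peak,

$$E_{(p)} = c + \left(1 - \tfrac{|p|}{100}\right)(d - c),$$

so $E_{(p)}$ is even in $p$: both branches attain the same response
height at the same $|p|$.  The inverse map has closed form: with
$s = \sqrt{-2\ln(1 - |p|/100)}$ the dose is $e - bs$ / $e + bfs$
(gaussian, ascending/descending) or $e\,e^{-bs}$ / $e\,e^{bfs}$
(loggaussian).  $|p| = 100$ is excluded — the corresponding dose is zero
or unbounded.

```{r zn}
zn <- biphasic_model("loggaussian", b = 0.410, c = 2.27, d = 79.31,
                     e = 2.43, f = 0.66)
edp(zn, c(-50, 0, 50))
```

## Fitting

`fit_biphasic()` estimates $(b, c, d, e, f)$ by bounded
Levenberg-Marquardt least squares, starting from moments of the dose
means (peak at the dose with the largest mean response; ascending width
from the half-height crossing; `multistart = TRUE` adds a small jitter
grid over $b_0$ and $f_0$, worth using when the curve is narrow relative
to the dilution spacing).  With `boxcox = TRUE` the same Box-Cox power
transform is applied to both the observations and the model predictions
("transform both sides"), the power $\lambda$ being chosen on the grid
$\{-1, -0.5, 0, 1/3, 0.5, 1\}$ by maximum profile likelihood; this
stabilises the roughly multiplicative variance of induction-factor data
without changing the curve's interpretation.  RSS is reported on the
fitting scale, and model-kind selection always compares untransformed
fits — transformed and untransformed RSS are incommensurable.

Degenerate inputs are contracts, not crashes: fewer than five distinct
dose levels is an error; constant response returns a flagged
non-converged result; a design that does not straddle the empirical peak
warns that the peak location is an extrapolation.  Dose-zero
observations are retained (the loggaussian takes its left-tail limit
$c$ there).

## Mixtures

A mixture ray is described by dose fractions $j_i = D_i / D_{mix}$
summing to 1 (`mixture_spec()`).  The laboratory "1:1 constant-ratio"
design mixes components in proportion to their individual $D_{(-50)}$
values — each component at an equal multiple of its own potency —
implemented by `constant_ratio_design()`, with weights for unequal
ratios such as 75:25.

Under concentration addition the additive mixture curve is, at each $p$,
the fraction-weighted harmonic mean of the component coordinates:

$$D_{add}(p) = \Big(\sum_i j_i / D_{(p),i}\Big)^{-1}, \qquad
  E_{add}(p) = \Big(\sum_i j_i / E_{(p),i}\Big)^{-1}.$$

The prediction is emitted as $(p, \text{dose}, \text{effect})$ rows
(`predict_curve()`), parameterised by $p$ rather than as a closed-form
function of dose — scaling a biphasic curve has no closed form in dose,
and any consumer needing response-at-dose interpolates monotonically in
$p$.

Two design choices here were genuinely open.  First, the weights in the
$E$ dimension: how total effect is apportioned among components is not
observable from mixture composition, and the dose fractions $j_i$ are
the only weights computable from it.  Reusing them preserves the exact
structural parallel between the two dimensions and keeps sham identities
exact; `additive_effect(weights = ...)` leaves room for alternatives.
Second, the *sham identity* is the framework's internal validation: a
"mixture" of a compound with itself must reproduce that compound's curve
exactly, for any number of components and any fractions.  With the
harmonic-mean formulation this holds as an algebraic identity, and the
test suite checks it to within $10^{-9}$ relative error over randomised
models — the in-silico counterpart of the experimental sham-mixture
validation.

## Departures from additivity

Given a fitted mixture curve on the total-dose axis, the combination
index is computed in both dimensions at any $p$:

$$CI_D(p) = \frac{D_{mix}(p)}{D_{add}(p)}, \qquad
  CI_E(p) = \frac{E_{add}(p)}{E_{mix}(p)}.$$

$CI_D < 1$ means the mixture needs less total dose than additively
expected (synergism in $D$).  The $E$-dimension ratio is oriented so
that $CI_E < 1$ likewise means *more* signal than expected — the
"interpretation" orientation.  The literal substitution of mixture
effects into the additivity equation yields the reciprocal; since either
reading is defensible, `ci_e_orientation = "literal"` inverts the ratio.
The default follows the interpretation under which a jointly synergistic
pair has $CI_D, CI_E < 1$, e.g. $CI_D = CI_E = 0.5$ (half the dose,
twice the signal) compounding to

$$CI_w = CI_D \cdot CI_E = 0.25 .$$

The weighted index $CI_w$ summarises both dimensions: it is magnified
when both depart the same way and tends to cancel when they counteract.
For risk management, $CI_w < 0.5$ is classified as synergism,
$CI_w > 2$ as antagonism, and the band between (boundaries inclusive) as
additive (`classify_management()`).  `ci_profile()` tabulates the
indices over a $p$ grid (the "extended p-CI plot",
`plot_ci_profile()`), and `polygonogram_summary()` collects pairwise
$CI_w$ values at representative levels $p \in \{-50, 0, +50\}$ into an
edge table for polygonogram rendering.

Statistical testing uses replicate-level indices (`ci_replicates()`):
the single-compound reference curves are pooled fits across replicates
(stabilising the reference), while each independent mixture experiment
is fitted separately, giving one $(CI_D, CI_E)$ pair per replicate per
$p$.  `test_departure()` then applies a one-sample two-sided t-test *on
the log scale* — a combination index is a positive ratio with a
multiplicative null, so $H_0\!: CI = 1$ becomes
$H_0\!: \mathbb{E}[\ln CI] = 0$ with $n - 1$ degrees of freedom.
Zero-variance degeneracies return $p = 1$ at the null and a flagged
$p = 0$ off it.  Tests are pointwise in $p$; no multiplicity correction
is applied across the grid.

## The synthetic-data generator

The generator emulates the laboratory design: 7-9 two-fold serial
dilutions per compound or ray (`dilution_series()`), 3-4 independent
replicates, and mean-corrected multiplicative lognormal noise at a
coefficient of variation around 0.1 — induction-factor scatter is
positive and roughly proportional to the signal; an additive-gaussian
option is retained for robustness checks.  `design_doses()` anchors the
top dose at $p = +99$ on the descending branch (signal decayed to 1% of
amplitude), so the series observes the full inhibition region; with a
narrower anchor the asymmetry parameter of a steep curve can sit on a
single dose level and become unidentifiable per replicate.

`simulate_mixture()` draws data from a ground-truth curve built by
scaling the additive prediction with constant indices
(`predict_with_interaction()`: dose $\times\, CI_D$, effect
$\div\, CI_E$), interpolated in $p$ over a dense grid
($[-99.5, 99.5]$, step $0.25$).  Because a factor-2 design spans a far
wider dose range than the $p$ parameterisation can reach (for a
loggaussian the dose tends to 0 only as $p \to -100$), doses below the
parameterised range take the analytic dose-to-zero limit — the weighted
harmonic mean of the component baselines divided by $CI_E$ — rather
than an endpoint clamp, which would bias the simulated baseline and
collapse dose levels.

What passing simulation-based tests shows, and what it does not: the
generator produces curves that are *exactly* of the fitted family with
*exactly* the assumed noise law, so recovery results certify the
estimation machinery, not the model's adequacy for any real biosensor.
Real data add speciation chemistry, plate effects, replicate-correlated
noise and curve shapes outside the split-Gaussian family, none of which
are emulated.

## Operating characteristics checked by the test suite

The acceptance tests exercise the pipeline at these problem sizes
(chosen to mirror the emulated design while keeping the default test
run quick):

* *Parameter recovery* — 200 simulated experiments from a steep
  loggaussian ($b = 0.4$, $c = 1$, $d = 80$, $e = 2.5$, $f = 0.7$),
  8 two-fold dilutions, 3 replicates, 10% CV noise: median relative
  error below 15% for every parameter and below 5% for the MPC.
* *Combination-index recovery* — 200 simulations each at
  $(CI_D, CI_E) = (0.5, 1)$ and $(1, 2)$ with 4 replicates: medians
  recovered within the 0.4-0.6 and 1.6-2.4 bands at
  $p \in \{-50, 0, 50\}$.
* *Type-I error* — 500 additive simulations; the replicate t-test on
  $CI_D$ at $p = 0$ rejects at the nominal 5% within binomial error.
  The calibration uses two components sharing $b, c, d, f$ and
  differing in MPC, so the additive null curve is itself exactly a
  loggaussian and the test is not confounded by structural lack of fit,
  and it uses the true generating components as the additive reference
  so the replicate log-indices entering the t-test are independent —
  the condition the t-test assumes.  Refitting noisy component
  references would shift all replicates of a simulation together and
  tests a different (correlated-error) question.

## Numerical notes and limitations

* Optimisation is bounded Levenberg-Marquardt on
  $(b, c, a = d - c, e, f)$ with $b, a, f > 0$, $c \ge 0$; convergence
  is flagged, never assumed, and non-converged fits carry `NA`
  estimates rather than stale values.
* Model-kind ties in `select_model()` break toward the loggaussian.
* A gaussian ascending-branch inversion below dose 0 is clipped to 0
  with a classed warning (`biphasicCI_dose_clipped`); geometric
  dilution designs starve a dose-scale gaussian of informative points,
  so linear spacing is advisable for that kind.
* The framework is agnostic to viability-control correction of the
  signal; corrected and uncorrected responses are handled identically.
* Out of scope: monotonic (log-logistic) families, Bliss independence,
  free-ion speciation corrections, and time-resolved extensions
  $ED_p = (D, E, t)$.
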