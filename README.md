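# biphasicCI

Mixture-effect analysis for inducible whole-cell biosensors and other
systems with **biphasic (inverted v-shaped) dose-response curves**.

Turn-on biosensors — e.g. a cyanobacterium carrying a metal-inducible
promoter fused to a luciferase operon — emit a signal that rises with
analyte dose up to a *maximum permissive concentration* (MPC) and then
declines as toxicity takes over.  Such curves defeat classical mixture
toxicology twice over: components reach *different maximal effects*, and
every effect level is attained at *two* doses, one per branch.  This
package implements a two-dimensional extension of Loewe additivity
(concentration addition) that handles both, for toxicologists,
biosensor developers and mixture-risk assessors.

## The method in brief

Each single-compound curve is fitted with a split peak model

    y(x) = c + (d − c) · exp(−½ (Δ/w)²),   w = b (left branch), b·f (right)

with Δ = x − e (`gaussian`) or Δ = ln x − ln e (`loggaussian`):
baseline `c`, peak `d` = E_max at the MPC `e`, ascending width `b`,
asymmetry `f`.  A fractional-effect scale p ∈ (−100, 100) indexes the
curve (p < 0 induction branch, 0 the peak, p > 0 inhibition branch) and
the effective dose becomes a **two-dimensional vector**

    ED_p = (D_(p), E_(p)),    E_(p) = c + (1 − |p|/100)(d − c),

the dose giving fractional effect p and the empirical signal attained
there.  For a mixture ray with dose fractions j_i summing to 1, the
additive expectation at every p is the fraction-weighted harmonic mean
in each dimension:

    D_add(p) = ( Σ j_i / D_(p),i )⁻¹,    E_add(p) = ( Σ j_i / E_(p),i )⁻¹,

and an observed mixture curve is scored by the **two-dimensional
combination index**

    CI_D(p) = D_mix(p) / D_add(p),   CI_E(p) = E_add(p) / E_mix(p),
    CI_w = CI_D · CI_E,

with CI < 1 synergism and CI > 1 antagonism in each dimension, a
replicate-level t-test on ln CI against additivity, and the
risk-management bands CI_w < 0.5 (synergism) / 0.5–2 (additive) /
CI_w > 2 (antagonism).  A sham mixture (a compound mixed with itself)
reproduces the single-compound curve *exactly* under this formulation —
the framework's built-in validation.

## Worked example

Simulate a metal with a known curve, refit it, then analyse a binary
mixture simulated with imposed dose-dimension synergism (CI_D = 0.5):

```r
library(biphasicCI)

zn <- biphasic_model("loggaussian", b = 0.7, c = 2.3, d = 79, e = 2.4, f = 0.8)
cu <- biphasic_model("loggaussian", b = 0.8, c = 1.0, d = 45, e = 9.0, f = 0.9)

dat_zn <- simulate_single(zn, design_doses(zn, 8, 2), cv = 0.1, n_rep = 3,
                          seed = 101, series_id = "Zn")
fit_zn <- select_model(response ~ dose, dat_zn, multistart = TRUE)
summary(fit_zn)
#> Biphasic dose-response fit (loggaussian)
#>
#> Parameters:
#>   Estimate Std. Error
#> b   0.7748      0.043
#> c   1.9470      1.006
#> d  73.0978      1.759
#> e   2.5246      0.092
#> f   0.7115      0.066
#>
#> RSS: 164.1  residual sd: 2.939  n: 24
#>
#> Effective-dose vectors ED_p = (D_(p), E_(p)):
#>    p  dose effect
#>  -50 1.014  37.52
#>    0 2.525  73.10
#>   50 4.831  37.52
```

The fit recovers the generating parameters (true MPC 2.4, estimate 2.52)
and prints the effective-dose vectors: e.g. at p = −50 a dose of
1.01 μM yields a signal of 37.5 BIF, half-way between baseline and peak
on the induction branch.

```r
spec <- constant_ratio_design(list(Zn = zn, Cu = cu))   # 1:1 by D_(-50)
spec
#> Mixture: Zn (0.2308) + Cu (0.7692)

truth <- predict_with_interaction(list(zn, cu), spec, ci_d = 0.5, ci_e = 1)
mix <- simulate_mixture(list(zn, cu), spec, ci_d = 0.5, ci_e = 1,
                        doses = design_doses(truth, 8, 2),
                        cv = 0.1, n_rep = 4, seed = 202, series_id = "Zn:Cu")
fit_mix <- select_model(response ~ dose, mix, multistart = TRUE)

ci_at_p(fit_mix$model, list(zn, cu), spec, c(-50, 0, 50))
#>     p  ci_d  ci_e  ci_w  category
#> 1 -50 0.522 0.945 0.493 synergism
#> 2   0 0.502 0.950 0.477 synergism
#> 3  50 0.486 0.945 0.459 synergism

rep_ci <- ci_replicates(mix, list(zn, cu), spec, p = 0, kind = fit_mix$kind)
test_departure(rep_ci$ci_d)[c("t", "p_value", "estimate")]
#>        t  p_value estimate
#> -24.1576   0.0002   0.5017
```

The imposed synergism is recovered — CI_D ≈ 0.50 across all three
fractional-effect levels, CI_E ≈ 0.95 (no effect-dimension departure
was imposed), CI_w ≈ 0.48 classifying the mixture as synergistic — and
the replicate t-test rejects additivity (p = 2·10⁻⁴) with a geometric
mean CI_D of 0.50.

`run_pipeline()` drives the same chain from a CSV plus a YAML/JSON
config and writes fit tables, ED_p tables, predicted curves, CI
profiles, a polygonogram edge table and a JSON run summary;
`plot()` and `plot_ci_profile()` draw the fitted curves and extended
p-CI plots.

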