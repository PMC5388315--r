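---
title: "Methods: estimating thermal parameters from stage-duration tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating thermal parameters from stage-duration tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermaldev)
```

## The data and what the models assume

The unit of analysis is a *stage-duration table*: for each life stage and
constant rearing temperature, the mean development duration of the
individuals that completed the stage, its standard error, the number of
individuals that entered the stage, and the fraction that survived it.
Everything downstream works on *developmental rates*, the reciprocals of
the per-temperature mean durations. Using `1/mean(D)` rather than
`mean(1/D)` is deliberate: the degree-day framework is linear in the rate
of the *average* individual, and published threshold tables are computed
this way, so the package is consistent with the quantity practitioners
actually report.

All models assume durations were measured at effectively constant
temperature, and that the survivors' mean duration is an unbiased summary
of the cohort (heavy differential mortality violates this, which is one
reason low-survival temperatures are excluded below).

## Which temperatures enter a fit

Two rules, both on by default for linear fits (`select_linear_range()`):

* **Survival rule** (`min_survival = 0.05`): a temperature where fewer
  than 5% of the cohort completes development is dropped. A handful of
  stressed survivors does not estimate the population rate; in the bundled
  dataset this removes 16 °C, where only 4% of eggs reached adulthood and
  the prepupal stage essentially arrested (over 100 days, consistent with
  a diapause response rather than Arrhenius-like slowing). When a table
  contains a whole-cohort stage (`immature_total`), its survival governs
  the rule for *every* stage: egg survival at 16 °C is 66%, but a
  temperature the cohort cannot complete is not usable evidence for any
  stage's linear segment.
* **Above-peak rule** (`exclude_above_peak = TRUE`): temperatures above
  the observed rate maximum are dropped, because past the peak the
  rate-temperature relation turns over and a line no longer applies. In
  the bundled dataset this removes 32 °C (the immature rate peaks at
  30 °C). For nonlinear fits this rule is off — those curves need the
  descending limb.

Explicit inclusion sets (`include_temperatures`) override both rules, so
either reading of an ambiguous published exclusion note is expressible.

## Linear models

The traditional model regresses rate on temperature and derives
`T_min = -a/b` and `K = 1/b`; their standard errors use the delta-method
forms `SE(T_min) = (r̄/b)·sqrt(S²/(N·r̄²) + SE_b²/b²)` and
`SE(K) = SE_b/b²`. The Ikemoto–Takai model regresses `D·T` on `D`, where
slope and intercept *are* `T_min` and `K` and need no delta method. Fits
are unweighted by default because the response is already a
per-temperature mean; weighting by sample size is available
(`weights = n`) but changes the estimand. The reported `p_value` is the
two-sided t test of the slope; `R²_adj = 1 − (1−R²)(N−1)/(N−2)`.

A fitted slope ≤ 0 leaves the threshold meaningless; the fit object is
returned with `flag = "nonpositive_slope"` and `NA` derived values instead
of raising, so batch reports over many stages complete and the flag
surfaces in the output table.

## Nonlinear curves and their optimization

Analytis, Brière-2 and Lactin-2 are fitted by bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) from 64 Latin-hypercube starting points inside the
bounds, keeping the best converged start. The default seed (20170228) makes
every fit reproducible; changing it moves results only to the extent the
multistart is incomplete, which the test suite bounds. Default bounds are
biologically motivated for temperate insects and wide enough not to bind
in well-determined problems: `t_min ∈ [0, 20]` °C, `t_max ∈ [30, 45]` °C,
limb exponents in `(0, 5]`, scale coefficients log-uniform over
`[1e-9, 1]`. Parameters that end within 1e-6 of a bound are listed in
`at_bounds`: with five rate means a four- or five-parameter curve is
weakly identified beyond the data range, and a pinned `t_max` is a
boundary solution to be read as "not determined by these data", not as an
estimate.

Degenerate evaluations are defined rather than left to chance: Analytis
and Brière-2 return 0 at and beyond their thresholds; the Brière `1/d`
power is applied only to the nonnegative base `(t_max − T)`; a negative
fitted `d` is accepted and evaluated as written. `R²_adj` uses `k` = the
number of free parameters (5, 4, 4); with five points the Analytis
residual degrees of freedom are zero and `R²_adj` is reported as `NaN`
rather than by any ad hoc convention.

`T_fast` is computed numerically: a 2000-point bracketing grid followed by
golden-section refinement to 1e-6 °C. For Analytis the closed form
`(n·t_max + m·t_min)/(n+m)` exists and the property suite checks the
numeric argmax against it to 1e-4 °C over random parameter draws. For
Lactin-2, `T_max` is reported as the fitted `t_max_param` and `T_min` as
the lower zero crossing of the formula, found by bracketed root search
below `T_fast`; absence of a sign change is flagged in the provenance
field instead of being silently imputed.

## The SSI model: structure and estimation design

The SSI rate is an Eyring-kinetics numerator divided by two inactivation
terms:

```
rate(T) = rho_phi · (T/T_opt) · exp[(ΔH_A/R)(1/T_opt − 1/T)]
          ─────────────────────────────────────────────────────────────
          1 + exp[(ΔH_L/R)(1/T_L − 1/T)] + exp[(ΔH_H/R)(1/T_H − 1/T)]
```

with all ratios in Kelvin and `R = 1.987` cal/(deg·mol) fixed. Interfaces
are Celsius throughout; Kelvin conversion happens only inside evaluation.
Two structural reductions shape the fitting procedure:

* `T_opt` is *defined* as the argmax of the enzyme-active probability (the
  inverted denominator), which has a closed form in
  `(T_L, T_H, ΔH_L, ΔH_H)` (`ssi_intrinsic_optimum()`). It is therefore
  never a free parameter, and the identity "fitted `t_opt` = activity
  argmax" is assertable, and asserted, in the tests.
* `rho_phi` enters linearly and is profiled out analytically.

That leaves five free parameters — `(T_L, T_H, ΔH_A, ΔH_L, ΔH_H)` — for
typically five rate means, and the unconstrained least-squares surface is
a flat ridge: solutions with half-inactivation placed just below the
coldest observation fit marginally better while being enzymologically
meaningless (they imply a substantially inactivated enzyme exactly where
the data are observed to follow the degree-day line, and they collapse
`T_opt` onto `T_fast`, erasing the distinction that motivates the model).
The fit is therefore regularized by the model's own central assumption:
over the degree-day segment the enzyme must be essentially fully active —
that is *why* that segment is linear. Concretely,
`enzyme_active_probability ≥ min_activity` (default 0.9) is enforced as a
smooth penalty at the linear-range temperatures (by default those the
above-peak rule retains). The derived temperatures are insensitive to the
exact threshold over 0.85–0.95; 0.9 is the round default for "negligible
inactivation".

The search itself is a nested grid + polish: `(T_L, T_H)` on a 0.5 °C grid
(data-relative ranges, `min(T) − [15, 2]` and `max(T) + [0.5, 8]`), an
inner bounded quasi-Newton minimization over the three enthalpies at each
node — started from a deterministic, data-informed point (activation
enthalpy from an Eyring-line regression on the linear-range rates;
inactivation magnitudes of −7e4 and 1e5 cal/mol, typical of published SSI
fits) plus seeded random starts — and a final local polish over all five
parameters. The deterministic start is probed at every node, so the seed
only ever improves the solution. On five rate means a fit takes well
under a minute on one core.

Because five points cannot identify three enthalpies, point estimates of
`ΔH_A`, `ΔH_L`, `ΔH_H` trade off along the fitted curve and should not be
interpreted individually; the meaningful outputs are the fitted curve and
the derived temperatures `T_opt` and `T_fast`. The reported `X²` is the
Pearson form `Σ(obs − fit)²/fit` (evaluating published SSI parameter sets
reproduces published `X²` values under this definition), and `R²_adj`
uses `k = 7`, hence `NaN` on five points.

## The cohort simulator

`simulate_cohort()` emulates the rearing design the analysis assumes:
`n_per_temp` individuals per temperature (default 100, the order of
published cohort sizes), independent Bernoulli survival, durations
`(1/rate(T)) · ε` with lognormal multiplicative noise of mean 1 (durations
are positive and right-skewed; the default `cv = 0.02` matches the
SE/mean magnitudes of rearing tables at n ≈ 100), and optional
daily-census discretization. The census convention is *ceiling*: a molt
observed at the 24 h check is recorded on that day, so recorded durations
round up; recovery experiments quantify the resulting upward duration
bias (< 1 day) and its propagation into `T_min` and `K`.

The simulator deliberately omits features of real data: no stage-to-stage
survival carryover, no among-individual rate autocorrelation across
stages, no fluctuating-temperature regimes, and mortality independent of
development time. Passing recovery tests therefore show that the
estimators are correct *under the model the analysis assumes* — unbiased
threshold recovery at `cv = 0.05`, exact recovery in the noiseless limit —
not that field data satisfy those assumptions.

## Problem sizes and runtime choices

The test and acceptance workloads are sized for a desk machine: property
loops run 100 random instances; recovery experiments use 50 replicates of
100 individuals at four temperatures; SSI fits use the default 0.5 °C
grid with 6 random starts per node. These sizes were chosen as the point
where results stabilize (doubling them changes no reported digit at the
precision asserted).

## Known limitations

* Linear-model SEs are delta-method approximations on four-point
  regressions; treat them as indicative.
* The SSI enthalpy estimates are not identified by typical rate tables
  (see above); only curve-level quantities are defended.
* Nonlinear upper thresholds from data ending at the rate peak are
  boundary-sensitive (watch `at_bounds`).
* The package fits per-temperature summary data; it does not model
  individual-level heterogeneity beyond what the simulator generates.
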