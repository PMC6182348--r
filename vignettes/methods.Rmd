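---
title: "Models and methods for abridged-table mortality forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for abridged-table mortality forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mortabridge)
```

## The statistical model

The package models the probability of death `q_xt` of the person
initially exposed at age group `x` in calendar year `t`. On an abridged
grid each group is represented by its midpoint age, so the 18-group
standard grid (`paper_age_grid()`) has ages 0.5, 3, 7.5, 12.5, …, 82.5.
The observation model is binomial: with `E_xt` initially exposed and
`d_xt` observed deaths,

```
d_xt ~ Binomial(E_xt, q_xt),    logit(q_xt) = eta_xt.
```

The logit link keeps every fitted and forecast probability inside
(0, 1), which the classical log-rate formulation does not guarantee at
high ages. Seven predictor structures are supported (`model_spec()`),
from the plain bilinear age–period model (LC) through two-term (LC2)
and cohort extensions (LCC, APC, RH) to the two-factor age-linear
structure (CBD) and its cohort generalisation (M8). Cohorts are indexed
by year of birth `c = t − x` with `x` the group midpoint, which on an
abridged grid yields half-integer labels for most groups; this is a
direct consequence of the midpoint convention, not an artefact.

**Assumptions.** Deaths are conditionally independent across cells
given the predictor; exposures are the binomial denominators ("initially
exposed to risk"), not central exposures; the predictor is constant
within an age group × year cell. The error term of the model family is
realised as the binomial sampling variation, which is why standardized
deviance residuals are the natural diagnostic.

## Estimation

`fit_mortality_model()` minimises the total binomial deviance

```
D = 2 * sum[ d log(d / dhat) + (E − d) log((E − d) / (E − dhat)) ]
```

by block-coordinate Newton updates: the static age profile, each age
loading, each period index, the cohort effect and (for M8) the constant
`x_c` each have a closed-form Newton step given the others. Numerical
safeguards, in the order they matter:

* **Damping.** Every block step is halved (up to 40 times) until the
  deviance does not increase, so the deviance trace is non-increasing
  by construction; the trace is stored in the fit for inspection.
* **Acceleration.** Plain block descent converges at a linear rate that
  becomes extremely slow along the weakly identified directions of the
  two-term and cohort models (the classic zigzag). After each sweep the
  fit tries extrapolating along the sweep's total parameter
  displacement, and along the displacement across the last two sweeps
  (which averages out the alternation), with a geometric ladder of step
  multipliers; a candidate is accepted only if it lowers the deviance,
  preserving monotonicity.
* **Stopping.** Iteration stops when the deviance decrease falls below
  `tol * (D + 1e-6)` with `tol = 1e-8`, or after `max_iter = 500`
  sweeps. Hitting the cap sets `converged = FALSE`; this is a reported
  state, not an error, and `predict_q()`, `forecast_probabilities()`
  and `compare_models()` refuse or flag such fits. Cohort models on
  abridged grids are the expected non-convergers: a five-year-wide
  cohort is observed in few cells, and different cohorts in very
  different numbers of cells.
* **Initialisation.** `a` is the per-age mean of the logit of the
  continuity-corrected empirical probability `(d + 0.5) / (E + 1)`
  (used only for initialisation — stored data are never modified);
  `b` starts uniform at `1/n_ages`; `k` comes from the leading singular
  component of the centred logit matrix, the second LC2 term from the
  residual matrix's leading component; cohort effects start at 0; CBD
  indices from per-year least squares of logit `q` on `(x − x̄)`;
  `x_c` starts above the oldest midpoint so the cohort loading is
  non-degenerate at the first γ update. Default fits are fully
  deterministic.
* **Cell weights.** Cells with `E = 0` are excluded from the deviance
  with a logged count.
* **Cohort pooling.** Cohorts observed in fewer than `min_cohort_cells
  = 3` cells are merged iteratively with the nearest cohort label (ties
  toward the earlier label). This mitigates the extreme-cohort sparsity
  that drives non-convergence, at the cost of a slightly coarser cohort
  index; the pooled label map is kept in the fit for prediction.

## Identifiability

The bilinear terms are invariant under `(b, k) → (b/s, s·k)` and under
index shifts absorbed into `a`. `apply_identifiability_constraints()`
normalises fitted (or any raw) parameters so the declared constraints
hold exactly — `Σb = 1` with the index zeroed at the first fitted year
(or sum-to-zero for RH/M8) and cohort effects zeroed at the first
cohort — without changing any predictor value. The transformation is
closed-form and idempotent; the package tests verify the predictor
moves by less than 1e−10.

**Degrees of freedom.** `residual_degrees_of_freedom()` counts cells
minus identifiable parameters. Each age–period bilinear term
contributes `n_ages + n_years − 2`; when two such terms are present the
pair loses 2 more, because mixing the terms (`b² += ε b¹` compensated
by `k¹ −= ε k²`, and vice versa) leaves the predictor unchanged — a
rotational freedom beyond the per-term normalisations. APC loses one
parameter to the exact age + cohort − period collinearity (cohort
labels are affine in `t − x` by construction). The convention is
validated in the test suite against the numerical rank of the
linearised predictor on small grids; on very small grids the cohort
models carry more nominal parameters than cells and the closed-form
count goes negative, so rank equivalence is checked wherever the count
is non-negative.

## Hold-out validation and diagnostics

`holdout_split()` assigns the first `ceiling(0.75 T)` years to
training; for 33 years this is the 25/8 split. `compare_models()`
fits each candidate on the training block, forecasts its indices over
the validation years (central forecasts only — interval bounds play no
role in scoring), and reports RMSE and MAPE of forecast vs observed
probabilities, alongside the same measures for the fitted training
surface (fitted values, not re-predictions). MAPE requires strictly
positive observed probabilities; a zero cell is an error by default
(`drop_zero_cells = TRUE` opts into exclusion) because silent dropping
changes the denominator invisibly.

Standardized deviance residuals are the signed square roots of the
per-cell deviance contributions. Under a well-specified model they are
approximately standard normal, so about 95.5% should fall in (−2, 2)
and about 99% in (−2.5, 2.5); `deviance_residuals()` flags cells
outside both bands and `residual_series()` arranges them by age, period
or cohort for dispersion plots.

## Index forecasting

The level index of every model is forecast as a random walk with drift
(drift = mean of first differences, sigma = their standard deviation),
the second LC2 index as a stationary AR(1) about a mean via conditional
least squares. Two deliberate choices:

* When the AR(1) estimate for a second index is non-stationary
  (`|phi| >= 1` — the realised index trended instead of reverting), the
  comparison and pipeline paths fall back to the random walk with
  drift. The CBD-type slope index is always treated as a random walk,
  since it trends like the level index.
* Prediction intervals reflect index-process error only (`z·σ·√s` for
  the random walk, the standard AR(1) forecast variance otherwise), not
  parameter uncertainty — the original Lee-Carter convention. With two
  indices the probability bounds combine per-index bounds by monotone
  interval arithmetic, choosing per cell the bound that moves the
  predictor down (up) according to the sign of the age loading; this
  ignores the correlation between indices and is therefore
  conservative.

For cohort models, forecast cells belong to cohorts never observed in
fitting; their effect is frozen at the last estimated cohort, with a
warning. This path is best-effort: cohort-model forecasting on abridged
grids inherits all the estimation fragility described above.

An opt-in automatic order choice (`fit_index_model(kind = "auto")`)
selects by corrected AIC among {RW+drift, AR(1)+mean, ARIMA(1,1,0),
ARIMA(0,1,1)}, with custom orders delegated to `stats::arima()`.

## Life-table construction and indicators

`build_life_table()` uses the person-years convention
`L = n(l − d) + a·n·d` with `a_frac = 0.5` by default (mid-interval
deaths) and configurable per group, since realistic infant deaths occur
early in the interval. The grid has no open-ended final interval, so by
default the last group is closed with `q = 1` and the closing age
recorded as omega; the Lorenz/Gini constructions need total extinction.
Whether source tables close their last group this way is generally
unknowable from the published tables; the closure affects only the mass
placed in the final group.

The Lorenz curve plots cumulative death share `N_i` against cumulative
lived-years share `Y_i`, with the mean age at death within a group
taken as `lower + a_frac · width` — consistent with the person-years
convention, since no finer information exists within a group. The
abridged Gini is the exact trapezoidal functional of these points. The
complete-table expression (`gini_complete()`), built from `f_x =
(l_0 − l_x)/l_0` and `g_x = (T_0 − T_x − x·l_x)/T_0`, is exact for
death distributions concentrated strictly before the closing age and a
good approximation for realistic human mortality on fine grids (the
tests verify agreement with the trapezoidal Gini within 0.02 on smooth
1-year tables); it is *not* a general-purpose Gini — for distributions
with substantial mass in the closing interval, or long flat tails, the
two formulas diverge, which is why the abridged formula is the default
throughout the package.

`modal_age_interval()` returns the group with maximal life-table
deaths among groups starting at or above `min_age = 10` (ties toward
the youngest). The default excludes infancy deliberately: the adult
mode is the longevity indicator of interest even when infant deaths are
numerous; set `min_age = 0` for the global mode. Modal intervals are
reported per year; aggregating them over multi-year periods is left to
the caller, as any aggregation rule (majority, first, last) is a
presentation choice.

## The synthetic-data generator

`make_ground_truth()` defines the world the tests assume: a known
logit-bilinear surface with binomial observation noise. The age
profiles are smooth parametric shapes — an exponential infant decline,
a log-linear (Gompertz-type) adult rise and, for the `male_like`
preset, a Gaussian young-adult hump centred near age 27 whose age
loading is negative exactly on the groups with midpoints in [15, 39]
(mortality at those ages worsens while overall mortality improves);
`female_like` has strictly positive loadings. Defaults: 18 groups ×
33 years (1973–2005), exposures constant at 1e5 per cell (an optional
age profile exists), period-index drift −0.3 and innovation sd 0.4 in
logit units per year, second-index AR(1) with phi 0.6 and sd 0.15.
These were chosen once to produce mid-transition mortality levels —
infant `q` near 0.03 falling over the period, old-age `q` near 0.4,
life expectancy in the high 60s rising through the 70s — with an
index signal large relative to binomial noise at 1e5 exposures; no
claim is made of matching any country's estimates. One integer seed
drives the index paths and the binomial draws; identical seeds give
bitwise-identical data.

What the generator does **not** emulate: census-interpolation artefacts
in exposures, age misstatement and heaping, migration, cohort effects
(unless a cohort model truth is constructed by hand) and
heteroscedastic exposure patterns. Passing recovery tests therefore
demonstrates correctness of the estimation machinery under the model's
own assumptions, not robustness to the measurement problems of real
vital registration.

## Problem sizes and runtime choices

The test suite and the acceptance script run the full 18 × 33 grid with
1e5 exposures for recovery and calibration checks (a fit takes well
under a second), 100 seeded random inputs for the brute-force oracle
comparisons, 1000 simulated futures for interval coverage, and grids up
to 5 × 5 for the rank-oracle validation of the degrees-of-freedom
convention. These sizes were chosen as the smallest at which the
stochastic checks are stable to their stated tolerances.

## Known limitations

* Cohort-effect models (LCC, RH, M8) frequently fail to converge on
  abridged grids; the package reports this honestly rather than
  returning a half-fitted object, but offers no remedy beyond cohort
  pooling.
* Prediction intervals understate uncertainty (no parameter error, no
  model error) and overstate it jointly for two-index models (no
  correlation); both are inherited from the interval convention used.
* The LC2 second term is weakly identified when the data are truly
  one-term; its parameters should be interpreted through predictions,
  not element-wise.
* Indicators on forecast years are computed from central probability
  paths; banding the indicators through the interval bounds is possible
  but compounds the conservatism noted above.
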