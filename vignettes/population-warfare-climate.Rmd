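---
title: "Coupled population–warfare–climate dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled population–warfare–climate dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(andeandyn)
```

## The scientific problem

Pre-industrial complex societies repeatedly show *boom-and-bust*
demographic trajectories: several centuries of population growth followed
by a sustained decline. Two broad families of explanation compete. In
one, an exogenous environmental driver (drought, flooding, a shift in the
mean hydroclimate state) moves the carrying capacity of the landscape and
the population follows. In the other — the structural-demographic view —
population growth itself breeds internal conflict, and warfare mortality
and its effect on productivity close an endogenous feedback loop that can
generate collapse without any climatic push.

`andeandyn` implements a discrete-time dynamical framework for
discriminating between these mechanisms from three proxy time series on a
common multi-decadal grid:

* a **paleodemographic proxy** `N` — summed probability distributions
  (SPDs) of calibrated radiocarbon dates, a relative index of population
  level, in both normalized and unnormalized variants;
* a **warfare-intensity index** `W` — an ordinal defensive-settlement
  score per chrono-cultural period (0/1/2 per evidence category, summed
  to a 0–6 range), translated to an annual step function;
* a **hydroclimate proxy** `C` — e.g. an annually resolved lithic
  (terrestrial clast) concentration from a marine core, where high values
  indicate El Niño-like wet coastal conditions and low values La
  Niña-like states (the models are agnostic about the sign: the climate
  coefficients absorb the direction).

The package does **not** build SPDs: radiocarbon calibration, binning and
rolling means are upstream (they belong to dedicated tools such as
`rcarbon`), and the package starts from proxy curves.

## The six model variants

All models are Ricker-type one-step maps, `X_t = X_{t-1} e^{rate}`, with
the rate depending on the state and forcings at the previous step. For
the population response:

| variant | log rate | parameters |
|---|---|---|
| `pop_climate` | $r_N\,(1 - N/k + \alpha C)$ | $r_N, k, \alpha$ |
| `pop_warfare` | $r_N\,(1 - N/k) - \beta W$ | $r_N, k, \beta$ |
| `pop_climate_warfare` | $r_N\,(1 - N/k + \alpha C + \gamma W)$ | $r_N, k, \alpha, \gamma$ |

and for the warfare response:

| variant | log rate | parameters |
|---|---|---|
| `war_basic` | $\lambda N - \mu$ | $\lambda, \mu$ |
| `war_additive_climate` | $\lambda N + \psi C - \mu$ | $\lambda, \psi, \mu$ |
| `war_pressure` | $\lambda N / C - \mu$ | $\lambda, \mu$ |

$r_N$ is the maximum per-capita reproductive rate and $k$ the carrying
capacity; $\alpha$ is a *lateral perturbation*: climate shifts the
equilibrium $k(1+\alpha C)$ rather than the growth rate directly.
$\beta$ is direct warfare mortality, $\gamma$ the effect of warfare on
land productivity, $\lambda$ the population-driven conflict-onset rate,
$\mu$ the exponential conflict decay, and $\psi$ an additive climate
effect on conflict. `war_pressure` replaces population size by
*population pressure*, the ratio of population to resource availability.
Every forcing enters at lag one step, matching the difference-equation
structure.

The variants nest: `pop_climate_warfare` with $\gamma = 0$ is
`pop_climate`; with $\alpha = 0$ it equals `pop_warfare` at
$\beta = -r_N\gamma$; `war_additive_climate` with $\psi = 0$ and
`war_pressure` at constant $C = 1$ both reduce to `war_basic`. The test
suite asserts these identities exactly.

One typographic ambiguity deserves a note: in the warfare-mortality
population model the $-\beta W$ term could be read either inside the
exponent or as a subtraction from the updated population. The package
places it in the exponent — the reading under which the log-transformed
model is the fitted rate equation — and offers the subtractive reading
behind `warfare_term = "subtract"` in `step_state()` and
`simulate_trajectory()` for sensitivity analysis. The subtractive map can
produce non-positive populations and is never used in fitting.

## Preprocessing

* **Smoothing.** Annual warfare and climate series are smoothed with a
  cubic smoothing spline (`stats::smooth.spline`), with `spar = 0.90`
  for the ordinal warfare index and `spar = 0.65` for the climate proxy
  as analysis defaults. `spar` maps monotonically to the roughness
  penalty, so the residual sum of squares against the raw data is
  non-decreasing in `spar`; constant and exactly linear series are fixed
  points. Heavily smoothed warfare curves can overshoot the ordinal
  range, so fitted values are clipped back to [0, 6].
* **Warfare encoding.** Period codes are expanded to an annual step
  function under a half-open convention: a period owns its start year
  and excludes its end year, which makes boundaries unambiguous. Period
  year boundaries are a user-supplied table — they are not hard-coded.
  Smoothing is applied to the annual series *before* resampling.
* **Resampling.** Series are evaluated on the uniform analysis grid
  (default step 25 years) by linear interpolation; the source series are
  already smoothed, so higher-order interpolation would add nothing.
  Resampling is idempotent on the target grid.
* **Log rates.** The response variables are one-step log differences,
  $\log X_t - \log X_{t-1}$, stamped at $t$ so that they align with
  predictors at $t - \text{step}$. Because the raw warfare index can be
  0, a configurable floor (default 0.1) raises sub-floor values before
  the log transform; every use is reported with a message.

## Fitting, selection and validation

Parameters are estimated by nonlinear least squares on the rate scale:
the observed log rate is regressed on the variant's rate expression with
Levenberg–Marquardt minimization (`minpack.lm`). Practical details that
matter:

* **Positivity.** $r_N, k, \lambda, \mu$ are positive by definition and
  are optimized on the log scale (a soft constraint that never fights
  the optimizer); the sign-free coefficients are optimized directly.
* **Multistart.** Nonlinear least squares on short series is
  initialization-sensitive, so by default a grid of starts is used:
  $r_N \in \{0.05, 0.2, 0.5, 1\}$, $k \in \{0.5, 1, 2\}\times\max(N)$,
  sign-free coefficients $\pm\{0.01, 0.1, 1\}$, $\lambda$ scaled so that
  $\lambda\,\overline{|driver|} \in \{0.05, 0.5, 5\}$ and
  $\mu \in \{0.01, 0.1, 1\}$. Starts are ranked by their initial RSS,
  the optimizer runs from the best ten, and the lowest final RSS wins.
* **Tolerances.** Relative function and step tolerances are $10^{-10}$
  with at most $10^4$ function evaluations, fixed for reproducibility.
  Each run has an iteration budget of 150; if it is exhausted the
  optimizer restarts once from the final point, and a relative deviance
  improvement below $10^{-8}$ is accepted as convergence. This matters
  for *misspecified* variants, whose optimum can lie along a flat
  direction (e.g. $\log r_N \to -\infty$ with $r_N/k$ fixed); the fit is
  then deviance-stationary and honestly usable for model comparison,
  but parameter values on such a ridge should not be interpreted.
* **Selection.** Models are ranked by the Gaussian BIC
  $n\ln(\mathrm{RSS}/n) + p\ln n$; the additive constant
  $n\ln(2\pi) + n$ is dropped since only differences on a common
  response matter. Ties are broken by fewer parameters, then by the
  higher coefficient of prediction. Comparison across different
  responses (or different $n$) is refused.
* **Validation.** Each fitted model is re-run as a *total trajectory*:
  started from the first observed value and iterated with observed
  exogenous covariates but its own simulated endogenous state — never
  re-anchored to data. The simulation is scored with the coefficient of
  prediction $\sigma^2 = 1 - \sum(O_i^* - O_i)^2 / \sum(\bar O - O_i)^2$,
  which is 1 for perfect prediction, 0 for a mean-only predictor and
  negative when the trajectory is worse than the mean. This is a much
  harsher test than the in-sample $R^2$ of the rate regression, because
  one-step errors compound along the trajectory.
* **Numerical guards.** Rate exponents are clipped at $\pm 50$ with a
  warning (extreme trial parameters during optimization would otherwise
  overflow `exp`); trajectories that exceed a configurable cap abort
  with an error naming the step; the population-pressure ratio refuses
  climate values at or below $10^{-8}$.
* **Confidence bands.** Trajectory plots can carry a parametric
  bootstrap band: parameter vectors are drawn from the asymptotic
  normal approximation on the optimizer's transformed scale, each draw
  is re-simulated, and pointwise quantiles are taken. This construction
  is this package's own choice; diverging draws are dropped.

## The synthetic-data generator

Because the real proxy series cannot be bundled, the package generates
coupled series with known ground truth, and every claim in the test
suite is made against such data. The generator emulates:

* a smooth positive population series with a rise-and-fall shape,
  produced by the model equations themselves;
* a slowly varying positive warfare series driven by the coupled
  warfare variant;
* a positive autocorrelated climate proxy — constant, linear trend,
  stationary AR(1) (level 35, marginal sd 5, lag-1 correlation 0.8 by
  default, emulating a percent-scale lithic record), or an AR(1) with a
  mean-state regime shift, emulating a multicentennial change such as a
  sustained La Niña-like phase.

Observation error is multiplicative lognormal on both endogenous series
(default sd 0.01), so log rates carry additive Gaussian noise — exactly
the error structure the least-squares layer assumes. This choice makes
the fitting model well-specified on synthetic data, which is what a
recovery experiment should isolate. The latent trajectories are
deterministic given the climate draw, so changing the noise level never
changes the truth, and a scenario plus seed is bit-reproducible.

Three presets define the study conditions used throughout the tests:

* `scenario_northern_like()` — 36 points, AD 50–925: climate-driven
  population (`pop_climate`, $r_N = 0.3$, $k = 0.35$, $\alpha = 0.05$)
  under a wet-to-dry regime shift at AD 650, with
  `war_additive_climate` warfare. The series length matches a 875-year
  window at 25-year steps.
* `scenario_southern_like()` — 40 points, AD 250–1225: warfare-driven
  population (`pop_warfare`, $\beta = 0.05$) coupled to
  population-pressure warfare (`war_pressure`, $\lambda = 6$,
  $\mu = 0.05$), with a mid-series climate regime shift.
* `scenario_boom_bust()` — the full productivity coupling
  (`pop_climate_warfare` + `war_basic`), tuned to a single interior
  population maximum with warfare still rising through the collapse
  phase.

Preset parameter values were chosen once to land in the qualitative
regimes just described (multi-century rise and sustained decline, an
O(1) population index, warfare within a plausible 0–8 band, climate
effects resolvable above the observation noise) and are not tuning
knobs.

What the generator does *not* emulate — and therefore what passing
recovery tests cannot certify about real data: radiocarbon calibration
wiggles and taphonomic loss in SPDs, the strong serial correlation that
heavy smoothing induces in real proxies (synthetic noise is independent
across steps), errors-in-variables in the covariates beyond the small
lognormal term, and any misalignment between the warfare chronology and
the SPD timescale. Results on real series should lean on the
total-trajectory $\sigma^2$, which punishes structural error, rather
than on in-sample $R^2$.

## Experiment sizes in the test suite

The test and acceptance suites run, among smaller checks: noise-free
simulate-then-fit recovery for all six variants (relative error at most
$10^{-6}$); a 200-replicate recovery experiment at noise sd 0.01 and
$n = 36$ (median absolute relative error of $r_N$ and $k$ under 10%); a
100-replicate-per-regime BIC selection experiment between the climate-
and warfare-driven population variants (each generating variant must be
ranked first in at least 90% of replicates); and a selection-consistency
check that the recovery fraction does not decrease from $n = 36$ to
$n = 150$. These problem sizes were chosen so the whole suite completes
in a couple of minutes on one CPU while keeping Monte-Carlo error well
below the asserted margins.

## Known limitations

* The BIC constant convention and the optimizer's internals differ
  across software, so absolute BIC values are not comparable across
  implementations — only differences within one comparison table are
  meaningful.
* Misspecified variants can converge onto parameter ridges (see above);
  their RSS/BIC are valid, their parameter values are not
  interpretable.
* The coefficient of prediction requires a non-constant observed
  series, and a diverging validation trajectory is reported as
  $\sigma^2 = -\infty$ with a flag rather than silently dropped.
* The pipeline treats normalized and unnormalized SPD variants as
  parallel analyses and never averages them; disagreement between the
  two is itself a diagnostic of calibration sensitivity.
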