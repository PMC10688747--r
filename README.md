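# andeandyn

Coupled population–warfare–climate dynamics for paleodemographic time
series.

`andeandyn` is for quantitative archaeologists and population ecologists
who want to ask, from proxy time series alone, *what drove a
pre-industrial boom-and-bust*: an exogenous hydroclimate shift acting on
the carrying capacity, or an endogenous structural-demographic feedback
between population growth and warfare. It takes three aligned series —
a paleodemographic SPD proxy `N` (normalized and unnormalized variants),
an ordinal warfare-intensity index `W` (0–6, from defensive-settlement
coding), and a hydroclimate proxy `C` — and fits, compares and validates
six discrete-time Ricker-type models.

## The models

All variants are one-step maps `X_t = X_{t-1} · exp(rate)` with the rate
driven by the previous step. Population response:

    pop_climate            rate = rN (1 − N/k + α C)
    pop_warfare            rate = rN (1 − N/k) − β W
    pop_climate_warfare    rate = rN (1 − N/k + α C + γ W)

Warfare response:

    war_basic              rate = λ N − μ
    war_additive_climate   rate = λ N + ψ C − μ
    war_pressure           rate = λ N / C − μ

Parameters are estimated by nonlinear least squares on the log rates of
change (`log X_t − log X_{t−1}`), with multistart Levenberg–Marquardt
and soft positivity constraints on `rN, k, λ, μ`. Models are ranked by
Gaussian BIC, `n ln(RSS/n) + p ln n`, and every fit is validated by
simulating its *total trajectory* from the first observed value
(simulated endogenous state, observed exogenous covariates) and scoring
it with the coefficient of prediction

    σ² = 1 − Σ(Oᵢ* − Oᵢ)² / Σ(Ō − Oᵢ)² ,

which is 1 for perfect prediction, 0 for a mean-only predictor, and
negative when the model trajectory is worse than the mean.

Preprocessing utilities convert raw inputs into the analysis frame:
cubic smoothing splines (`spar` 0.90 for warfare, 0.65 for climate by
default), period-coded warfare expanded to an annual step function,
resampling to a 25-year grid, and log growth rates. A synthetic-data
module generates coupled series with known ground truth for parameter
recovery and model-selection experiments; no external data are needed to
build or test the package.

## Worked example

A self-contained run on a synthetic southern-like scenario (warfare-
driven population, population-pressure warfare, 40 points at 25-year
steps):

```r
library(andeandyn)

config <- analysis_config(area = "southern-like demo",
                          scenario = scenario_southern_like(seed = 42))
report <- run_analysis(config)
report
#> <andean_report> area 'southern-like demo': 40 aligned points, 12 fits
#>   population_SPDn    best: pop_warfare          BIC  -335.71  R2  0.991  sigma2  0.999
#>   warfare_SPDn       best: war_pressure         BIC  -325.16  R2  0.943  sigma2  1.000
#>   population_SPDnn   best: pop_warfare          BIC  -328.94  R2  0.989  sigma2  0.999
#>   warfare_SPDnn      best: war_pressure         BIC  -323.77  R2  0.941  sigma2  1.000

report$comparisons$population_SPDn[, c("model", "rN", "k", "beta",
                                       "r_squared", "bic", "delta_bic",
                                       "sigma2")]
#>                 model       rN        k   beta r_squared  bic delta_bic sigma2
#> 1         pop_warfare 3.50e-01 1.00e+00 0.0507     0.991 -336      0.00  0.999
#> 2 pop_climate_warfare 3.42e-01 9.84e-01     NA     0.991 -332      3.49  0.999
#> 3         pop_climate 1.66e-05 5.27e-05     NA     0.874 -232    103.78     NA
```

The generating model (`pop_warfare`) is ranked first by BIC; its
parameter estimates sit on the scenario truth (`rN = 0.35`, `k = 1`,
`β = 0.05`) and its simulated total trajectory explains essentially all
the variance (`σ² ≈ 1`). The richer nested variant pays the BIC penalty
for its unused climate term (ΔBIC ≈ 3.5, close to the ln n ≈ 3.7 cost
of one extra parameter at almost no RSS gain), and the misspecified
climate-only model
collapses onto a parameter ridge — it is reported, flagged as
non-converged, and left unvalidated (`sigma2 = NA`) rather than dressed
up.

`write_report(report, "out/")` writes the aligned series table, one
comparison CSV per response, per-model trajectory CSVs and a JSON run
manifest; `plot_report(report)` returns ggplot panels and one
observed-vs-predicted figure per fit. A thin command-line wrapper is
installed at `inst/cli/andeandyn-cli` (subcommands `generate` and
`run`).

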