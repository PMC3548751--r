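# uniadapt

Evidence synthesis for clinical prediction models: **uniadapt** combines
previously published *univariable* predictor–outcome associations (log
odds ratios, often reconstructable from baseline 2×2 tables) with the
individual participant data (IPD) at hand when estimating
**multivariable** logistic-regression coefficients.

## The methods

For a predictor of interest, write β̂<sub>u|I</sub> and β̂<sub>m|I</sub>
for its univariable and multivariable (adjusted) coefficients estimated
in the IPD, and β̂<sub>u|L</sub> for the pooled univariable association
from the literature (random-effects meta-analysis of the literature
studies plus the IPD's own univariable estimate). The package implements:

* **Analytic (Greenland/Steyerberg) adaptation** —
  β̂<sub>m|L</sub> = β̂<sub>m|I</sub> + c(β̂<sub>u|L</sub> − β̂<sub>u|I</sub>)
  with variance Var(β̂<sub>u|L</sub>) + Var(β̂<sub>m|I</sub>) −
  Var(β̂<sub>u|I</sub>) at the default c = 1. This variance can go
  negative; the package flags, never clips.
* **Improved (bootstrap) adaptation** — the univariable→multivariable
  shift is modelled as δ ~ N(μ<sub>δ</sub>, σ²<sub>δ</sub>) and estimated
  by refitting both models on bootstrap resamples of the IPD; then
  β̂<sub>m|L</sub> = μ̂<sub>u|L</sub> + μ̂<sub>δ</sub> with variance
  σ̂²<sub>u|L</sub> + σ̂²<sub>δ</sub>, which is non-negative by
  construction. The resampled fits are either maximum likelihood
  (*no prior*) or posterior modes under weakly informative Cauchy priors
  (scale 10 intercept / 2.5 slopes on the standardized scale,
  *weakly informative prior*), which keep estimates finite under
  separation and stabilise the adaptation in small samples.

A Monte-Carlo framework (`scenario_config()`, `run_scenario()`) generates
IPD and literature studies from a reference model
(Pr(y=1) = logit⁻¹(−3.43 + 1.45·x₁ + 1.18·x₂), 9% incidence) and compares
the approaches by percentage bias, MSE and 90%-interval coverage. See the
methods vignette (`vignettes/adaptation-methods.Rmd`) for the model,
assumptions and design choices.

## Worked example

Adapt a literature association for `x1` using the improved method with
the weakly informative prior:

```r
library(uniadapt)

ipd <- generate_ipd(scenario_config(n_ipd = 300, seed = 5))     # small IPD
lit <- read_literature_csv(
  system.file("extdata", "synthetic_literature_estimates.csv",
              package = "uniadapt")
)

row <- adapt_association(
  ipd, lit, outcome = "y", predictor = "x1",
  covariates = c("x1", "x2"),
  method = "improved-weak", pooling = "random",
  n_bootstrap = 1000, seed = 42
)
dplyr::glimpse(row)
#> Rows: 1
#> Columns: 15
#> $ predictor              <chr> "x1"
#> $ method                 <chr> "improved_weak_prior"
#> $ beta                   <dbl> 1.371754
#> $ variance               <dbl> 0.02388371
#> $ conf.low               <dbl> 1.117553
#> $ conf.high              <dbl> 1.625956
#> $ negative_variance_flag <lgl> FALSE
#> $ mu_delta               <dbl> 0.1595049
#> $ sigma2_delta           <dbl> 0.01230354
#> $ n_flagged              <int> 0
#> $ pooling                <chr> "random"
#> $ pooled_mu              <dbl> 1.21225
#> $ pooled_variance        <dbl> 0.01158017
#> $ tau2                   <dbl> 0
#> $ seed                   <int> 42
```

Reading the output: the univariable estimates (four literature studies
plus the IPD's own) pool to 1.212 on the log-odds scale, the bootstrap
estimates the univariable→multivariable shift as μ̂δ = 0.160 with
σ̂²δ = 0.012, and the adapted multivariable association is
1.212 + 0.160 = 1.372 with variance 0.0116 + 0.0123 = 0.0239
(90% CI 1.12–1.63) — close to the generating multivariable coefficient
1.45, and far more precise than the IPD-only fit at n = 300. No
bootstrap replicate was separation-flagged.

A small method comparison (no bootstrap methods, 200 repetitions):

```r
res <- run_scenario(
  scenario_config(n_ipd = 100, n_reps = 200, seed = 1),
  methods = c("no_meta", "gs")
)
tidy(res)
#> # A tibble: 2 x 11
#>   n_ipd n_lit sigma_h   rho method     pb   mse coverage n_negative_variance n_reps_effective n_separation
#>   <int> <int>   <dbl> <dbl> <chr>   <dbl> <dbl>    <dbl>               <int>            <int>        <int>
#> 1   100   500       0     0 no_meta 11.1  0.512    0.92                    0              200            1
#> 2   100   500       0     0 gs       5.33 0.161    0.929                   4              200            1
```

Ignoring the literature (`no_meta`) overestimates the coefficient by 11%
with MSE 0.51; the analytic adaptation halves the bias and cuts the MSE
to 0.16, at the cost of 4 repetitions with an invalid (negative)
variance. `autoplot(res)` draws the per-method interval plot.

A shell front end with `adapt` and `simulate` subcommands is provided in
`scripts/uniadapt.R` (see its header for flags).

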