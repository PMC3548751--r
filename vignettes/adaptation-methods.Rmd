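---
title: "Adapting published univariable associations: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adapting published univariable associations: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uniadapt)
```

## The problem

Clinical prediction models for a binary outcome are usually fitted by
multivariable logistic regression on whatever individual participant data
(IPD) the modeller has collected. The literature, meanwhile, is full of
*univariable* predictor–outcome associations — log odds ratios derivable
from baseline tables or reconstructed 2×2 counts — that cannot be entered
into a multivariable model directly because they are unadjusted. uniadapt
implements estimators that put this evidence to work anyway.

Write $\hat\beta_{u|I}$ and $\hat\beta_{m|I}$ for the univariable and
multivariable coefficients of a predictor estimated in the IPD, and
$\hat\beta_{u|L}$ for the pooled univariable association from the
literature. Throughout, "adaptation" means the shift from the univariable
to the multivariable scale.

## Estimators

**Analytic (Greenland/Steyerberg, `gs_adapt()`).** The adapted coefficient
is
$$\hat\beta_{m|L} = \hat\beta_{m|I} + c\,(\hat\beta_{u|L} - \hat\beta_{u|I}),$$
with the classical variance
$\widehat{\mathrm{Var}}(\hat\beta_{u|L}) + \widehat{\mathrm{Var}}(\hat\beta_{m|I}) - \widehat{\mathrm{Var}}(\hat\beta_{u|I})$
at the default weight $c = 1$. That variance implicitly assumes
$\mathrm{Cov}(\hat\beta_{m|I}, \hat\beta_{u|I}) =
\mathrm{Var}(\hat\beta_{u|I})$; when the multivariable fit happens to look
more precise than the univariable one, the formula goes *negative*. The
package never clips this: the value is returned with
`negative_variance_flag` set, and the simulation machinery counts such
repetitions. For $c \ne 1$ we generalise the variance as
$\mathrm{Var}(\hat\beta_{m|I}) + c^2(\mathrm{Var}(\hat\beta_{u|L}) -
\mathrm{Var}(\hat\beta_{u|I}))$ — our own construction, chosen so that
$c=1$ reproduces the classical formula exactly and $c=0$ degenerates to
the IPD-only fit. A data-driven choice of $c$ is out of scope.

**Improved (bootstrap) adaptation (`bootstrap_adaptation()` +
`improved_adapt()`).** Instead of the covariance assumption, the
adaptation is treated as a random quantity
$\delta \sim N(\mu_\delta, \sigma^2_\delta)$ estimated by resampling the
IPD: each bootstrap sample is refitted univariably and multivariably and
the difference of the two coefficients recorded. The adapted association
is then
$$\hat\beta_{m|L} = \hat\mu_{u|L} + \hat\mu_\delta,\qquad
\widehat{\mathrm{Var}}(\hat\beta_{m|L}) = \hat\sigma^2_{u|L} + \hat\sigma^2_\delta,$$
a sum of two non-negative components — the negative-variance pathology is
structurally impossible. The two variants differ only in how the resampled
models are fitted: plain maximum likelihood (*no prior*), or posterior
modes under weakly informative Cauchy priors (*weakly informative prior*).

**Pooling.** $\hat\mu_{u|L}, \hat\sigma^2_{u|L}$ come from a
random-effects meta-analysis (DerSimonian–Laird, via
`metafor::rma.uni()`) of the literature estimates *plus* the IPD
univariable estimate — the robust configuration used for every method
here. Fixed-effect pooling is available (`pool_fixed()`), and reduces the
random-effects result exactly when the inputs are homogeneous.

## The weakly informative prior

Small IPDs with few events make resampled ML fits unstable: a bootstrap
sample can be completely separated, in which case the MLE diverges and the
recorded adaptation is essentially arbitrary — this is what produces the
astronomically heavy tails of the no-prior variant. The remedy is the
Gelman et al. (2008) default prior: independent Cauchy distributions
centred at zero, scale 10 for the intercept and 2.5 for every other
coefficient, applied after centring binary inputs and rescaling continuous
inputs to standard deviation 0.5. The posterior mode is finite under any
separation pattern.

Implementation choices (`fit_logistic()` with
`prior_weakly_informative()`):

* The prior is applied on the standardized scale by default
  (`standardize = TRUE`), matching the reference implementation's
  convention; coefficients and covariance are mapped back to the original
  scale through the affine transform. Whether that implementation's
  internal standardization was active in the original runs is not
  documented; we assume yes, since it is the default.
* The mode is found by Newton ascent on the *exact* log-posterior (the
  Cauchy term is not approximated by an EM-type scheme). The Cauchy
  contribution to the Hessian changes sign at $|b| = s$, so steps are
  safeguarded by backtracking line search with a gradient-direction
  fallback; convergence requires a log-posterior gradient norm below
  $10^{-6}$ (typically $10^{-10}$ is reached). The covariance is the
  negative inverse Hessian at the mode.
* A dense two-dimensional grid search over the raw-scale posterior is kept
  in the test suite as an independent oracle for the optimizer.

## Separation: flagging and retention

A maximum-likelihood fit is flagged as (quasi-)separated when the IRLS
optimizer fails to converge or any standardized-scale coefficient exceeds
10 in absolute value. MAP fits are flagged only on optimizer failure,
because their estimates are finite by construction. Flags propagate;
nothing raises.

What is *done* with flagged fits is a design decision with visible
consequences:

* **Bootstrap replicates** (within `bootstrap_adaptation()`): retained by
  default and counted in `n_flagged`. Dropping them would quietly repair
  the no-prior variant, whose instability is a finding, not a bug. An
  `exclude_flagged` switch exists but is off by default. Resamples with a
  constant outcome are redrawn (count in `n_redrawn`), keeping the number
  of replicates fixed.
* **Simulation repetitions** (within `run_scenario()`): a repetition fails
  for a method only when an ML fit it uses did not *converge*; failures
  are excluded and reported through `n_reps_effective`. Converged fits
  with extreme coefficients are legitimate draws of the estimator and are
  retained — they are exactly the small-sample behaviour the adaptation
  methods are designed to fix. Separation-flag counts are reported
  alongside (`n_separation`). A consequence worth knowing: with ~9 events
  per 100 subjects, the across-repetition MSE of the ML-based methods is
  heavy-tailed, so its realisation over 500 repetitions varies
  substantially between seeds.

## The synthetic-data generator

`generate_ipd()` draws $(x_1, x_2)$ bivariate normal with unit variances
and correlation $\rho$ (via the usual linear transform of independent
normals) and sets $y = 1$ with probability
$\mathrm{logit}^{-1}(b_0 + b_1 x_1 + b_2 x_2)$. The defaults
$b = (-3.43, 1.45, 1.18)$ with $\rho = 0$ give an average incidence of 9%
and a marginal (univariable) $x_1$ association of about 1.25 — the gap
1.45 − 1.25 ≈ 0.20 is the true adaptation that the bootstrap estimates.
`generate_literature()` draws, for each of 4 studies, a study-specific
$b_{1}$ from $N(b_1, \sigma_h^2)$, simulates $N_L$ subjects and returns
the univariable ML estimate; the IPD always uses the homogeneous $b_1$,
so heterogeneity enters only through the literature.

What the generator deliberately does *not* emulate: real literature
studies differ in case mix, predictor definitions and measurement error,
and published 2×2 tables carry rounding and selective-reporting artefacts.
Passing tests on these synthetic conditions show the estimators behave as
designed under exchangeability and controlled heterogeneity; they do not
certify performance under the messier forms of between-study
incomparability.

## Simulation metrics and sizes

`run_scenario()` evaluates each method by percentage bias
$(\bar{\hat\beta}_1 - b_1)/b_1 \times 100\%$, mean squared error
$(\bar{\hat\beta}_1 - b_1)^2 + \widehat{SE}(\hat\beta_1)^2$ — where the
spread term is read as the empirical across-repetition variance with
denominator $n-1$, the standard simulation convention — and coverage of
the nominal 90% Wald interval ($z = 1.6449$). Repetitions with a negative
analytic variance cannot form an interval: they keep their point estimate
for bias and MSE, are excluded from the coverage denominator, and are
counted in `n_negative_variance`.

Reproducibility: one root seed draws a 31-bit sub-seed per repetition, so
a scenario is bit-identical across runs and method subsets see identical
data. Default problem sizes are those of the study conditions: 500
repetitions per scenario, 4 literature studies, and bootstrap
$B = 1000$ by default — the package's evaluation scripts use $B = 200$,
which resolves $\sigma^2_\delta$ well enough that the improved-method MSE
is stable to well under its Monte-Carlo spread. Unit tests use smaller
repetition counts chosen to keep each property check sharp but quick;
the vignette and README examples state the sizes they use.

## Degenerate inputs and tie-breaks

* Constant outcome: an error everywhere (the model is not estimable);
  bootstrap resamples and generated literature datasets with a constant
  outcome are redrawn and counted.
* A predictor column with zero variance is left unscaled by the
  standardization (divisor 1) and its coefficient is driven to the prior
  mode 0 under MAP; under ML it is dropped by rank detection in the QR.
* Zero cells in a 2×2 table: 0.5 added to all four cells of that table
  (Haldane–Anscombe); a zero margin after correction is an error.
* Pooling a single estimate returns it unchanged with $\tau^2 = 0$.
* `mse()` refuses fewer than two estimates (its spread term is an
  empirical variance); `percentage_bias()` refuses a zero truth.

## Known limitations

* Coefficients are adapted one predictor at a time; joint adaptation with
  cross-coefficient covariance is not attempted.
* Only univariable literature evidence is supported — published
  *multivariable* associations, time-to-event models and missing-data
  handling are out of scope.
* The exchangeability assumption is load-bearing: under strong
  heterogeneity the adaptation estimated in the IPD need not transfer to
  the literature, and interval coverage degrades accordingly.
* The evaluation concerns coefficient recovery, not downstream predictive
  performance (calibration or discrimination) of a model built from the
  adapted coefficients.
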