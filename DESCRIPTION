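Package: uniadapt
Title: Adapting Published Univariable Associations for Multivariable
    Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines previously published univariable predictor-outcome
    associations (log odds ratios) with individual participant data when
    estimating multivariable logistic-regression coefficients. Implements
    the analytic Greenland/Steyerberg adaptation and an improved,
    bootstrap-based adaptation method in which the univariable-to-
    multivariable shift is estimated as a normal distribution from
    resampled model fits, optionally stabilised by weakly informative
    Cauchy priors on the regression coefficients. Includes fixed- and
    random-effects pooling of literature estimates, 2-by-2 table
    conversion, and a Monte-Carlo simulation framework that evaluates
    the estimators by percentage bias, mean squared error and confidence
    interval coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    metafor,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
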