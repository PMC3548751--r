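# The adaptation estimators: the analytic Greenland/Steyerberg method and
# the bootstrap-based improved adaptation method, which shift a pooled
# univariable literature association onto the multivariable scale using the
# univariable-to-multivariable change observed in the IPD.

#' Greenland/Steyerberg analytic adaptation
#'
#' Adapts a pooled univariable literature association to the multivariable
#' scale using the analytic recipe
#' `beta_m|L = beta_m|I + c * (beta_u|L - beta_u|I)` with variance
#' `Var(beta_m|I) + c^2 * (Var(beta_u|L) - Var(beta_u|I))`, which at the
#' default weight `c = 1` is the classical
#' `Var(beta_u|L) + Var(beta_m|I) - Var(beta_u|I)`. This variance can be
#' negative — a known pathology of the method, arising when the
#' multivariable fit appears more precise than the univariable one. A
#' negative result is flagged (`negative_variance_flag`), never clipped.
#'
#' @param pooled A [pool_random()] / [pool_fixed()] summary of the
#'   univariable associations (literature, usually plus the IPD).
#' @param fit_u Univariable `logistic_fit` of the predictor in the IPD.
#' @param fit_m Multivariable `logistic_fit` including the predictor.
#' @param predictor Name of the predictor being adapted.
#' @param c_weight Weight on the literature-minus-IPD difference;
#'   `c_weight = 1` (default) is the unweighted original method,
#'   `c_weight = 0` ignores the literature entirely.
#' @return An `adapted_association` object; see [improved_adapt()] for the
#'   shared structure.
#' @examples
#' d <- generate_ipd(scenario_config(n_ipd = 500, seed = 3))
#' fu <- fit_logistic(d, "y", "x1")
#' fm <- fit_logistic(d, "y", c("x1", "x2"))
#' lit <- univariable_estimates(c(1.2, 1.3), c(0.05, 0.04))
#' gs_adapt(pool_random(lit), fu, fm, "x1")
#' @export
gs_adapt <- function(pooled, fit_u, fit_m, predictor, c_weight = 1) {
  stopifnot(inherits(pooled, "pooled_estimate"))
  u <- coef_variance(fit_u, predictor)
  m <- coef_variance(fit_m, predictor)
  beta <- m$beta + c_weight * (pooled$mu - u$beta)
  variance <- m$variance + c_weight^2 * (pooled$variance - u$variance)
  new_adapted_association(
    beta = beta, variance = variance, method = "GS", c_weight = c_weight,
    diagnostics = list(separation_u = fit_u$separation,
                       separation_m = fit_m$separation)
  )
}

#' Bootstrap estimate of the adaptation distribution
#'
#' Estimates the distribution `N(mu_delta, sigma2_delta)` of the shift from
#' univariable to multivariable association by resampling the IPD with
#' replacement: in each bootstrap sample both models are refitted (maximum
#' likelihood, or MAP under [prior_weakly_informative()]) and the
#' difference `beta_m - beta_u` for the predictor is recorded. `mu_delta`
#' and `sigma2_delta` are the mean and sample variance of these
#' differences.
#'
#' Resamples with a degenerate outcome (all events or none) cannot be
#' fitted and are redrawn, keeping the number of usable replicates fixed;
#' the redraw count is recorded. Replicates with a separation-flagged fit
#' are kept by default and counted in `n_flagged` — without a prior such
#' replicates are exactly the source of the unstable, heavy-tailed
#' adaptations that motivate the weakly informative prior. Set
#' `exclude_flagged = TRUE` to drop them instead.
#'
#' @inheritParams fit_logistic
#' @param predictor The predictor whose adaptation is wanted; must be an
#'   element of `covariates`.
#' @param covariates All predictors of the multivariable model.
#' @param n_bootstrap Number of bootstrap replicates (>= 2). Default 1000.
#' @param seed Optional integer seed for the resampling.
#' @param exclude_flagged Drop separation-flagged replicates from the
#'   moments? Default `FALSE`.
#' @return An `adaptation_dist` object: `mu_delta`, `sigma2_delta`,
#'   `n_bootstrap`, `n_flagged`, `n_redrawn`, `prior`, and the vector of
#'   replicate `deltas`.
#' @examples
#' d <- generate_ipd(scenario_config(n_ipd = 200, seed = 4))
#' bootstrap_adaptation(d, "y", "x1", c("x1", "x2"),
#'   prior = prior_weakly_informative(), n_bootstrap = 50, seed = 1
#' )
#' @export
bootstrap_adaptation <- function(data, outcome, predictor, covariates,
                                 prior = prior_weakly_informative(),
                                 n_bootstrap = 1000, seed = NULL,
                                 exclude_flagged = FALSE) {
  if (!predictor %in% covariates) {
    abort("`predictor` must be one of `covariates`.")
  }
  if (n_bootstrap < 2) abort("`n_bootstrap` must be at least 2.")
  xy <- check_ipd(data, outcome, covariates)
  n <- length(xy$y)
  if (sum(xy$y) < 2 || sum(1 - xy$y) < 2) {
    abort("Bootstrap adaptation needs at least 2 events and 2 non-events.")
  }
  if (!is.null(seed)) set.seed(seed)
  j <- match(predictor, covariates)
  use_map <- prior$kind != "none"

  deltas <- numeric(n_bootstrap)
  flagged <- logical(n_bootstrap)
  n_redrawn <- 0L
  for (b in seq_len(n_bootstrap)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      yb <- xy$y[idx]
      if (any(yb == 1) && any(yb == 0)) break
      n_redrawn <- n_redrawn + 1L
    }
    Xb <- xy$X[idx, , drop = FALSE]
    if (use_map) {
      fm <- map_engine(Xb, yb, prior$intercept_scale, prior$coefficient_scale,
                       prior$standardize)
      fu <- map_engine(Xb[, j, drop = FALSE], yb, prior$intercept_scale,
                       prior$coefficient_scale, prior$standardize)
    } else {
      fm <- ml_engine(Xb, yb)
      fu <- ml_engine(Xb[, j, drop = FALSE], yb)
    }
    deltas[b] <- fm$coefficients[j + 1] - fu$coefficients[2]
    flagged[b] <- fm$separation || fu$separation
  }
  used <- if (exclude_flagged) !flagged else rep(TRUE, n_bootstrap)
  if (sum(used) < 2) {
    abort("Fewer than 2 usable bootstrap replicates after excluding flagged fits.")
  }
  structure(
    list(
      mu_delta = mean(deltas[used]),
      sigma2_delta = var(deltas[used]),
      n_bootstrap = n_bootstrap,
      n_flagged = sum(flagged),
      n_redrawn = n_redrawn,
      exclude_flagged = exclude_flagged,
      prior = prior,
      predictor = predictor,
      deltas = deltas
    ),
    class = "adaptation_dist"
  )
}

#' Improved adaptation of a pooled univariable association
#'
#' The improved adaptation method: the adapted multivariable association is
#' `mu_u|L + mu_delta` with variance `sigma^2_u|L + sigma^2_delta`, treating
#' the literature summary and the bootstrap-estimated adaptation as
#' independent normal components. Unlike the analytic
#' Greenland/Steyerberg variance, this sum is non-negative by construction.
#'
#' @param pooled A `pooled_estimate` of the univariable associations.
#' @param adaptation An `adaptation_dist` from [bootstrap_adaptation()].
#' @return An `adapted_association`: `beta`, `variance`, `method`
#'   (`"improved_no_prior"` or `"improved_weak_prior"` according to the
#'   adaptation's prior), `negative_variance_flag` (always `FALSE` here),
#'   and bootstrap diagnostics. `tidy()` returns a one-row tibble with a
#'   90% confidence interval.
#' @examples
#' d <- generate_ipd(scenario_config(n_ipd = 200, seed = 4))
#' ad <- bootstrap_adaptation(d, "y", "x1", c("x1", "x2"),
#'   n_bootstrap = 50, seed = 1
#' )
#' lit <- univariable_estimates(c(1.2, 1.3), c(0.05, 0.04))
#' improved_adapt(pool_random(lit), ad)
#' @export
improved_adapt <- function(pooled, adaptation) {
  stopifnot(inherits(pooled, "pooled_estimate"),
            inherits(adaptation, "adaptation_dist"))
  if (adaptation$sigma2_delta < 0) abort("`sigma2_delta` must be non-negative.")
  method <- if (adaptation$prior$kind == "none") {
    "improved_no_prior"
  } else {
    "improved_weak_prior"
  }
  new_adapted_association(
    beta = pooled$mu + adaptation$mu_delta,
    variance = pooled$variance + adaptation$sigma2_delta,
    method = method, c_weight = NA_real_,
    diagnostics = list(n_bootstrap = adaptation$n_bootstrap,
                       n_flagged = adaptation$n_flagged)
  )
}

new_adapted_association <- function(beta, variance, method, c_weight,
                                    diagnostics = list()) {
  structure(
    list(
      beta = beta,
      variance = variance,
      method = method,
      c_weight = c_weight,
      negative_variance_flag = variance < 0,
      diagnostics = diagnostics
    ),
    class = "adapted_association"
  )
}

#' @method print adaptation_dist
#' @export
print.adaptation_dist <- function(x, ...) {
  cat(sprintf(
    "<adaptation_dist (%s): mu_delta = %.4f, sigma2_delta = %.5f, B = %d, flagged = %d, redrawn = %d>\n",
    if (x$prior$kind == "none") "no prior" else "weakly informative prior",
    x$mu_delta, x$sigma2_delta, x$n_bootstrap, x$n_flagged, x$n_redrawn
  ))
  invisible(x)
}

#' @describeIn improved_adapt One-row tibble for an `adaptation_dist`:
#'   `mu_delta`, `sigma2_delta`, `n_bootstrap`, `n_flagged`, `n_redrawn`.
#' @param x An `adaptation_dist` or `adapted_association`.
#' @param ... Unused.
#' @export
tidy.adaptation_dist <- function(x, ...) {
  tibble(
    mu_delta = x$mu_delta, sigma2_delta = x$sigma2_delta,
    n_bootstrap = x$n_bootstrap, n_flagged = x$n_flagged,
    n_redrawn = x$n_redrawn
  )
}

#' @method print adapted_association
#' @export
print.adapted_association <- function(x, ...) {
  cat(sprintf(
    "<adapted_association (%s): beta = %.4f, variance = %.5f%s>\n",
    x$method, x$beta, x$variance,
    if (x$negative_variance_flag) ", NEGATIVE variance" else ""
  ))
  invisible(x)
}

#' @describeIn improved_adapt One-row tibble: `method`, `beta`, `variance`,
#'   `conf.low`, `conf.high` (level `conf.level`, Wald; `NA` when the
#'   variance is negative), `negative_variance_flag`.
#' @param conf.level Confidence level for the Wald interval. Default 0.90.
#' @export
tidy.adapted_association <- function(x, conf.level = 0.90, ...) {
  z <- qnorm((1 + conf.level) / 2)
  se <- if (x$variance >= 0) sqrt(x$variance) else NA_real_
  tibble(
    method = x$method,
    beta = x$beta,
    variance = x$variance,
    conf.low = x$beta - z * se,
    conf.high = x$beta + z * se,
    negative_variance_flag = x$negative_variance_flag
  )
}

#' One-call adaptation of a literature association
#'
#' End-to-end driver behind the command-line `adapt` subcommand: pools the
#' literature univariable estimates together with the IPD univariable
#' estimate, and adapts the pooled association to the multivariable scale
#' with the chosen method.
#'
#' @inheritParams bootstrap_adaptation
#' @param literature A tibble of univariable estimates
#'   ([univariable_estimates()], [estimate_from_2x2()] or
#'   [read_literature_csv()]).
#' @param method `"gs"`, `"improved-noprior"` or `"improved-weak"`.
#' @param pooling `"random"` (default) or `"fixed"` effects pooling.
#' @param c_weight Weight for the GS method; ignored otherwise.
#' @param conf.level Confidence level of the reported Wald interval.
#' @param include_ipd Pool the IPD univariable estimate together with the
#'   literature (default `TRUE`, the robust configuration)?
#' @return A one-row tibble: `predictor`, `method`, `pooling`, `beta`,
#'   `variance`, `conf.low`, `conf.high`, `negative_variance_flag`,
#'   `mu_delta`, `sigma2_delta`, `n_flagged`, `seed`.
#' @examples
#' d <- generate_ipd(scenario_config(n_ipd = 300, seed = 5))
#' lit <- univariable_estimates(c(1.2, 1.3, 1.1), c(0.05, 0.04, 0.06))
#' adapt_association(d, lit, "y", "x1", c("x1", "x2"), method = "gs")
#' @export
adapt_association <- function(data, literature, outcome, predictor,
                              covariates,
                              method = c("gs", "improved-noprior",
                                         "improved-weak"),
                              pooling = c("random", "fixed"),
                              c_weight = 1, n_bootstrap = 1000,
                              seed = NULL, conf.level = 0.90,
                              include_ipd = TRUE) {
  method <- match.arg(method)
  pooling <- match.arg(pooling)
  prior <- switch(method,
    "gs" = prior_none(),
    "improved-noprior" = prior_none(),
    "improved-weak" = prior_weakly_informative()
  )
  fit_u <- fit_logistic(data, outcome, predictor, prior = prior)
  pool_set <- literature
  if (include_ipd) {
    u <- coef_variance(fit_u, predictor)
    pool_set <- dplyr::bind_rows(
      literature,
      univariable_estimates(u$beta, u$variance, source = "IPD",
                            study_id = "IPD")
    )
  }
  pooled <- if (pooling == "random") pool_random(pool_set) else pool_fixed(pool_set)

  if (method == "gs") {
    fit_m <- fit_logistic(data, outcome, covariates, prior = prior_none())
    adapted <- gs_adapt(pooled, fit_u, fit_m, predictor, c_weight = c_weight)
    extra <- tibble(mu_delta = NA_real_, sigma2_delta = NA_real_,
                    n_flagged = NA_integer_)
  } else {
    ad <- bootstrap_adaptation(data, outcome, predictor, covariates,
                               prior = prior, n_bootstrap = n_bootstrap,
                               seed = seed)
    adapted <- improved_adapt(pooled, ad)
    extra <- tibble(mu_delta = ad$mu_delta, sigma2_delta = ad$sigma2_delta,
                    n_flagged = ad$n_flagged)
  }
  dplyr::bind_cols(
    tibble(predictor = predictor),
    tidy(adapted, conf.level = conf.level),
    extra,
    tibble(pooling = pooling, pooled_mu = pooled$mu,
           pooled_variance = pooled$variance, tau2 = pooled$tau2,
           seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  )
}
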