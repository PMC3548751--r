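# Univariable and multivariable logistic regression on IPD: maximum
# likelihood through stats::glm.fit, and posterior-mode (MAP) estimation
# under weakly informative Cauchy priors through an exact-Newton optimizer.

# non-convergence, or a standardized-scale coefficient beyond this, marks a
# fit as (quasi-)separated
SEPARATION_THRESHOLD <- 10

#' Fit a logistic regression on individual participant data
#'
#' Fits the binary outcome on a chosen predictor subset, either by maximum
#' likelihood or — with [prior_weakly_informative()] — by posterior-mode
#' estimation under independent Cauchy priors. A single-predictor subset
#' gives the univariable association of that predictor; the full subset
#' gives its multivariable (adjusted) association.
#'
#' Separation (divergent maximum-likelihood estimates when a predictor
#' perfectly splits events from non-events) is detected and flagged rather
#' than raised: `separation` is set when the optimizer fails to converge or
#' any standardized-scale coefficient exceeds 10 in absolute value. Under
#' the Cauchy prior the posterior mode is always finite, so MAP fits on
#' separated data return usable coefficients.
#'
#' @param data Data frame with one row per subject; the outcome column must
#'   be coded 0/1 and all predictor columns numeric, without missing values.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor column names (non-empty).
#' @param prior A prior specification from [prior_none()] (default) or
#'   [prior_weakly_informative()].
#'
#' @return An object of class `logistic_fit` with elements `coefficients`
#'   (named, intercept first, log-odds scale), `vcov` (covariance matrix:
#'   inverse observed information at the ML estimate, or negative inverse
#'   Hessian of the log-posterior at the mode), `converged`, `separation`,
#'   `gradient_norm`, `prior`, `n`, `outcome`, `predictors`.
#'   [tidy()] gives a per-term tibble, [glance()] a one-row fit summary.
#'
#' @examples
#' d <- generate_ipd(scenario_config(n_ipd = 500, seed = 1))
#' fit_logistic(d, "y", c("x1", "x2"))
#' fit_logistic(d, "y", "x1", prior = prior_weakly_informative())
#' @export
fit_logistic <- function(data, outcome, predictors, prior = prior_none()) {
  xy <- check_ipd(data, outcome, predictors)
  if (!is_prior(prior)) abort("`prior` must be created by prior_none() or prior_weakly_informative().")
  eng <- if (prior$kind == "none") {
    ml_engine(xy$X, xy$y)
  } else {
    map_engine(xy$X, xy$y,
               intercept_scale = prior$intercept_scale,
               coefficient_scale = prior$coefficient_scale,
               standardize = prior$standardize)
  }
  new_logistic_fit(eng, prior = prior, outcome = outcome,
                   predictors = predictors, n = length(xy$y))
}

# ---- validation -----------------------------------------------------------

check_ipd <- function(data, outcome, predictors) {
  if (!is.data.frame(data)) abort("`data` must be a data frame of subjects.")
  if (length(predictors) < 1) abort("`predictors` must name at least one column.")
  missing_cols <- setdiff(c(outcome, predictors), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Column(s) not found in `data`: ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  y <- data[[outcome]]
  if (anyNA(data[c(outcome, predictors)])) {
    abort("Missing values are not supported; complete cases only.")
  }
  if (!is.numeric(y) || !all(y %in% c(0, 1))) {
    abort(sprintf("Outcome column `%s` must be coded 0/1.", outcome))
  }
  if (all(y == 0) || all(y == 1)) {
    abort("Outcome is constant (all events or all non-events); the model is not estimable.")
  }
  X <- as.matrix(data[predictors])
  if (!is.numeric(X)) abort("All predictor columns must be numeric.")
  list(X = X, y = as.numeric(y))
}

# ---- maximum likelihood ---------------------------------------------------

# X: predictor matrix without intercept column
ml_engine <- function(X, y) {
  Xi <- cbind("(Intercept)" = 1, X)
  fit <- suppressWarnings(glm.fit(Xi, y, family = binomial()))
  p <- ncol(Xi)
  covmat <- tryCatch(chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]),
                     error = function(e) matrix(NA_real_, p, p))
  dimnames(covmat) <- list(colnames(Xi), colnames(Xi))
  coefs <- fit$coefficients
  std <- standardize_info(X)
  b_std <- to_standardized(coefs, std)
  list(
    coefficients = coefs,
    vcov = covmat,
    converged = isTRUE(fit$converged),
    separation = !isTRUE(fit$converged) ||
      any(abs(b_std[-1]) > SEPARATION_THRESHOLD) ||
      abs(b_std[1]) > SEPARATION_THRESHOLD * 5,
    gradient_norm = NA_real_,
    method = "ml"
  )
}

# ---- Cauchy-prior posterior mode ------------------------------------------

# Gelman-style input standardization: continuous columns are centred and
# scaled to sd 0.5 (divide by 2 sd); binary columns are centred only.
standardize_info <- function(X) {
  ctr <- colMeans(X)
  scl <- rep(1, ncol(X))
  for (j in seq_len(ncol(X))) {
    if (length(unique(X[, j])) > 2) scl[j] <- 2 * sd(X[, j])
    if (!is.finite(scl[j]) || scl[j] == 0) scl[j] <- 1
  }
  list(center = ctr, scale = scl)
}

# map original-scale (intercept, slopes) to the standardized scale
to_standardized <- function(b, std) {
  c(b[1] + sum(b[-1] * std$center), b[-1] * std$scale)
}

# linear map A such that b_original = A %*% b_standardized
destandardize_matrix <- function(std) {
  p <- length(std$scale)
  A <- diag(c(1, 1 / std$scale), nrow = p + 1)
  A[1, -1] <- -std$center / std$scale
  A
}

# Newton ascent of the exact log-posterior: Bernoulli log-likelihood plus
# independent Cauchy log-densities. The Cauchy prior contribution to the
# Hessian can be positive for |b| > scale, so steps are safeguarded by
# backtracking on the objective and a gradient fallback.
map_engine <- function(X, y, intercept_scale = 10, coefficient_scale = 2.5,
                       standardize = TRUE, max_iter = 100, tol = 1e-9) {
  if (standardize) {
    std <- standardize_info(X)
    Z <- sweep(sweep(X, 2, std$center), 2, std$scale, "/")
  } else {
    std <- list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
    Z <- X
  }
  Zi <- cbind(1, Z)
  p <- ncol(Zi)
  scales <- c(intercept_scale, rep(coefficient_scale, ncol(X)))

  log_post <- function(b) {
    eta <- drop(Zi %*% b)
    # numerically safe log(1 + exp(eta))
    ll <- sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
    ll + sum(dcauchy(b, 0, scales, log = TRUE))
  }
  grad_hess <- function(b) {
    eta <- drop(Zi %*% b)
    mu <- plogis(eta)
    g <- drop(crossprod(Zi, y - mu)) - 2 * b / (scales^2 + b^2)
    w <- mu * (1 - mu)
    H <- -crossprod(Zi * w, Zi) +
      diag(-2 * (scales^2 - b^2) / (scales^2 + b^2)^2, p)
    list(g = g, H = H)
  }

  b <- numeric(p)
  f <- log_post(b)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    gh <- grad_hess(b)
    if (sqrt(sum(gh$g^2)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(gh$H, -gh$g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) step <- gh$g / sqrt(sum(gh$g^2))
    tt <- 1
    repeat {
      b_new <- b + tt * step
      f_new <- log_post(b_new)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      tt <- tt / 2
      if (tt < 1e-10) { b_new <- b; f_new <- f; break }
    }
    if (max(abs(b_new - b)) < 1e-12 && iter > 1) {
      b <- b_new; f <- f_new
      converged <- sqrt(sum(grad_hess(b)$g^2)) < 1e-6
      break
    }
    b <- b_new
    f <- f_new
  }
  gh <- grad_hess(b)
  gradient_norm <- sqrt(sum(gh$g^2))
  if (!converged) converged <- gradient_norm < 1e-6
  V_std <- tryCatch(solve(-gh$H), error = function(e) matrix(NA_real_, p, p))

  A <- destandardize_matrix(std)
  coefs <- drop(A %*% b)
  covmat <- A %*% V_std %*% t(A)
  nms <- c("(Intercept)", colnames(X))
  names(coefs) <- nms
  dimnames(covmat) <- list(nms, nms)
  list(
    coefficients = coefs,
    vcov = covmat,
    converged = converged,
    # the posterior mode is finite by construction, so only an optimizer
    # failure marks a MAP fit as unusable
    separation = !converged,
    gradient_norm = gradient_norm,
    method = "map"
  )
}

# ---- the fitted-object class ----------------------------------------------

new_logistic_fit <- function(engine, prior, outcome, predictors, n) {
  structure(
    list(
      coefficients = engine$coefficients,
      vcov = engine$vcov,
      converged = engine$converged,
      separation = engine$separation,
      gradient_norm = engine$gradient_norm,
      method = engine$method,
      prior = prior,
      outcome = outcome,
      predictors = predictors,
      n = n
    ),
    class = "logistic_fit"
  )
}

#' Extract one coefficient and its variance from a fit
#'
#' Convenience accessor used throughout the adaptation workflow, where
#' coefficients are adapted one predictor at a time.
#'
#' @param fit A `logistic_fit`.
#' @param predictor Predictor name; must be among the fitted terms.
#' @return A one-row tibble with columns `term`, `beta`, `variance`.
#' @examples
#' d <- generate_ipd(scenario_config(n_ipd = 300, seed = 2))
#' coef_variance(fit_logistic(d, "y", c("x1", "x2")), "x1")
#' @export
coef_variance <- function(fit, predictor) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!predictor %in% names(fit$coefficients)) {
    abort(sprintf("Predictor `%s` is not a term of this fit.", predictor))
  }
  tibble(
    term = predictor,
    beta = unname(fit$coefficients[predictor]),
    variance = unname(fit$vcov[predictor, predictor])
  )
}

#' @method print logistic_fit
#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit: %s, n = %d%s%s>\n",
    if (x$method == "ml") "maximum likelihood" else "Cauchy-prior posterior mode",
    x$n,
    if (!x$converged) ", NOT converged" else "",
    if (x$separation) ", separation flagged" else ""
  ))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @describeIn fit_logistic Per-term tibble: `term`, `estimate`,
#'   `std.error`.
#' @param x,object A `logistic_fit`.
#' @param ... Unused.
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = sqrt(pmax(diag(x$vcov), 0))
  )
}

#' @describeIn fit_logistic One-row tibble: `n`, `method`, `converged`,
#'   `separation`.
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble(
    n = x$n,
    method = x$method,
    converged = x$converged,
    separation = x$separation
  )
}
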