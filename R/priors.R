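#' Prior specifications for logistic model fitting
#'
#' `prior_none()` requests plain maximum-likelihood estimation.
#' `prior_weakly_informative()` requests posterior-mode (MAP) estimation
#' under independent, zero-centred Cauchy priors on all coefficients — the
#' weakly informative default of Gelman et al. (2008): scale 10 for the
#' intercept and 2.5 for every other coefficient, applied on a standardized
#' predictor scale. These priors keep coefficient estimates finite even
#' under complete separation, which is what stabilises bootstrap estimates
#' of the univariable-to-multivariable adaptation in small samples.
#'
#' @param intercept_scale Positive Cauchy scale for the intercept.
#'   Default 10.
#' @param coefficient_scale Positive Cauchy scale for all non-intercept
#'   coefficients. Default 2.5.
#' @param standardize Apply the prior on the standardized-input scale
#'   (continuous predictors centred and rescaled to standard deviation 0.5,
#'   binary predictors centred)? Coefficients are always reported back on
#'   the original scale. Default `TRUE`, matching the convention of the
#'   reference implementation in the *arm* package.
#'
#' @return An object of class `uniadapt_prior`.
#' @examples
#' prior_none()
#' prior_weakly_informative()
#' @export
prior_weakly_informative <- function(intercept_scale = 10,
                                     coefficient_scale = 2.5,
                                     standardize = TRUE) {
  if (!is.numeric(intercept_scale) || length(intercept_scale) != 1 ||
      intercept_scale <= 0) {
    abort("`intercept_scale` must be a single positive number.")
  }
  if (!is.numeric(coefficient_scale) || length(coefficient_scale) != 1 ||
      coefficient_scale <= 0) {
    abort("`coefficient_scale` must be a single positive number.")
  }
  structure(
    list(
      kind = "weakly_informative",
      intercept_scale = intercept_scale,
      coefficient_scale = coefficient_scale,
      standardize = isTRUE(standardize)
    ),
    class = "uniadapt_prior"
  )
}

#' @rdname prior_weakly_informative
#' @export
prior_none <- function() {
  structure(list(kind = "none"), class = "uniadapt_prior")
}

#' @method print uniadapt_prior
#' @export
print.uniadapt_prior <- function(x, ...) {
  if (x$kind == "none") {
    cat("<prior: none (maximum likelihood)>\n")
  } else {
    cat(sprintf(
      "<prior: weakly informative Cauchy (intercept scale %g, coefficient scale %g, %s)>\n",
      x$intercept_scale, x$coefficient_scale,
      if (x$standardize) "standardized inputs" else "raw inputs"
    ))
  }
  invisible(x)
}

is_prior <- function(x) inherits(x, "uniadapt_prior")
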