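# Univariable evidence: log odds ratios from 2x2 tables and their fixed- or
# random-effects pooling across literature studies and the IPD.

#' Build a table of univariable estimates
#'
#' The common currency of the package: one row per source (a literature
#' study or the IPD at hand) holding a univariable log odds ratio and its
#' variance.
#'
#' @param beta Numeric vector of log odds ratios.
#' @param variance Positive numeric vector of their variances.
#' @param source `"literature"` or `"IPD"` per estimate (recycled).
#' @param study_id Labels (recycled / autogenerated).
#' @return A tibble with columns `study_id`, `beta`, `variance`, `source`.
#' @examples
#' univariable_estimates(c(1.2, 1.4), c(0.05, 0.08))
#' @export
univariable_estimates <- function(beta, variance,
                                  source = "literature",
                                  study_id = NULL) {
  if (length(beta) != length(variance)) {
    abort("`beta` and `variance` must have the same length.")
  }
  if (any(!is.finite(variance)) || any(variance <= 0)) {
    abort("All `variance` values must be finite and positive.")
  }
  if (is.null(study_id)) study_id <- paste0("study_", seq_along(beta))
  out <- tibble(
    study_id = as.character(study_id),
    beta = as.numeric(beta),
    variance = as.numeric(variance),
    source = rep_len(as.character(source), length(beta))
  )
  bad <- setdiff(unique(out$source), c("literature", "IPD"))
  if (length(bad) > 0) abort('`source` must be "literature" or "IPD".')
  out
}

#' Univariable log odds ratios from 2x2 outcome-by-predictor tables
#'
#' Converts reconstructed 2x2 contingency tables — the typical form in
#' which published baseline tables yield predictor-outcome evidence — into
#' univariable estimates via the standard log odds ratio and its Woolf
#' variance `1/a + 1/b + 1/c + 1/d`. When any cell is zero, 0.5 is added to
#' all four cells of that table (Haldane-Anscombe correction) before the
#' formulas are applied.
#'
#' @param tables Data frame with one row per study and columns
#'   `events_exposed` (a), `nonevents_exposed` (b), `events_unexposed` (c),
#'   `nonevents_unexposed` (d), and optionally `study_id`.
#' @return A tibble of [univariable_estimates()], one row per input table.
#' @examples
#' estimate_from_2x2(data.frame(
#'   events_exposed = 10, nonevents_exposed = 90,
#'   events_unexposed = 5, nonevents_unexposed = 195
#' ))
#' @export
estimate_from_2x2 <- function(tables) {
  cols <- c("events_exposed", "nonevents_exposed",
            "events_unexposed", "nonevents_unexposed")
  if (!is.data.frame(tables) || !all(cols %in% names(tables))) {
    abort(paste0("`tables` must contain columns ",
                 paste(cols, collapse = ", "), "."))
  }
  cnt <- as.matrix(tables[cols])
  if (any(cnt < 0) || any(cnt != floor(cnt))) {
    abort("Cell counts must be non-negative integers.")
  }
  if (any(rowSums(cnt) == 0)) abort("Each table must have a positive total.")
  zero <- rowSums(cnt == 0) > 0
  cnt[zero, ] <- cnt[zero, , drop = FALSE] + 0.5
  a <- cnt[, 1]; b <- cnt[, 2]; c_ <- cnt[, 3]; d <- cnt[, 4]
  if (any(a + b == 0) || any(c_ + d == 0) ||
      any(a + c_ == 0) || any(b + d == 0)) {
    abort("A table has a zero margin even after continuity correction.")
  }
  ids <- if ("study_id" %in% names(tables)) {
    as.character(tables$study_id)
  } else {
    paste0("study_", seq_len(nrow(cnt)))
  }
  univariable_estimates(
    beta = log((a * d) / (b * c_)),
    variance = 1 / a + 1 / b + 1 / c_ + 1 / d,
    source = "literature",
    study_id = ids
  )
}

#' Pool univariable estimates across sources
#'
#' `pool_fixed()` performs inverse-variance (common-effect) pooling;
#' `pool_random()` performs random-effects pooling with the
#' DerSimonian-Laird moment estimator of the between-study variance tau^2.
#' Both are computed with [metafor::rma.uni()]. The pooled summary is the
#' `N(mu_u|L, sigma^2_u|L)` that the adaptation methods shift toward the
#' multivariable scale; following the robust configuration, the pooled set
#' normally contains the literature studies plus the IPD univariable
#' estimate.
#'
#' @param estimates A tibble from [univariable_estimates()],
#'   [estimate_from_2x2()] or [read_literature_csv()] (columns `beta` and
#'   `variance`; at least one row).
#' @return An object of class `pooled_estimate` with elements `mu`,
#'   `variance`, `tau2`, `method`, `k`.
#' @examples
#' est <- univariable_estimates(c(0.0, 1.0), c(0.01, 0.04))
#' pool_fixed(est)
#' pool_random(est)
#' @export
pool_random <- function(estimates) {
  pool_impl(estimates, method = "random")
}

#' @rdname pool_random
#' @export
pool_fixed <- function(estimates) {
  pool_impl(estimates, method = "fixed")
}

pool_impl <- function(estimates, method) {
  if (!is.data.frame(estimates) ||
      !all(c("beta", "variance") %in% names(estimates))) {
    abort("`estimates` must be a data frame with columns `beta` and `variance`.")
  }
  k <- nrow(estimates)
  if (k == 0) abort("Cannot pool an empty set of estimates.")
  if (any(estimates$variance <= 0)) abort("All variances must be positive.")
  if (k == 1) {
    return(new_pooled_estimate(estimates$beta, estimates$variance, 0,
                               method, 1L))
  }
  fit <- suppressWarnings(metafor::rma.uni(
    yi = estimates$beta, vi = estimates$variance,
    method = if (method == "random") "DL" else "EE"
  ))
  new_pooled_estimate(as.numeric(fit$beta), as.numeric(fit$se)^2,
                      as.numeric(fit$tau2), method, as.integer(k))
}

new_pooled_estimate <- function(mu, variance, tau2, method, k) {
  structure(
    list(mu = mu, variance = variance, tau2 = tau2, method = method, k = k),
    class = "pooled_estimate"
  )
}

#' @method print pooled_estimate
#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "<pooled_estimate (%s effects, k = %d): mu = %.4f, variance = %.5f, tau2 = %.5f>\n",
    x$method, x$k, x$mu, x$variance, x$tau2
  ))
  invisible(x)
}

#' @describeIn pool_random One-row tibble: `mu`, `variance`, `tau2`,
#'   `method`, `k`.
#' @param x A `pooled_estimate`.
#' @param ... Unused.
#' @export
tidy.pooled_estimate <- function(x, ...) {
  tibble(mu = x$mu, variance = x$variance, tau2 = x$tau2,
         method = x$method, k = x$k)
}
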