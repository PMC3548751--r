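# ggplot2 views of the two result types: the bootstrap adaptation
# distribution and the per-method estimate distributions of a scenario.

#' Plot a bootstrap adaptation distribution
#'
#' Histogram of the bootstrap replicates of `beta_m - beta_u` with the
#' fitted normal `N(mu_delta, sigma2_delta)` overlaid. Heavy or wild tails
#' here are the signature of separation in the resampled fits — the
#' motivation for the weakly informative prior.
#'
#' @param object An `adaptation_dist` from [bootstrap_adaptation()].
#' @param bins Histogram bins. Default 30.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adaptation_dist <- function(object, bins = 30, ...) {
  d <- tibble(delta = object$deltas)
  dens <- function(x) {
    stats::dnorm(x, object$mu_delta, sqrt(object$sigma2_delta))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(.data$density)),
      bins = bins, fill = "grey70", colour = "grey40"
    ) +
    ggplot2::stat_function(fun = dens, colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(
      x = "bootstrap adaptation (beta_m - beta_u)", y = "density",
      title = sprintf("Adaptation distribution: N(%.3f, %.4f)",
                      object$mu_delta, object$sigma2_delta),
      subtitle = sprintf("B = %d, flagged = %d", object$n_bootstrap,
                         object$n_flagged)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-method estimates of a simulation scenario
#'
#' Interval plot in the style of a method-comparison figure: for each
#' method, the mean estimate across repetitions with a central 90% range,
#' against the true coefficient (dashed line).
#'
#' @param object A `scenario_result` from [run_scenario()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scenario_result <- function(object, ...) {
  est <- dplyr::filter(object$estimates, !.data$failed)
  s <- dplyr::summarise(
    dplyr::group_by(est, .data$method),
    mean = mean(.data$beta),
    lo = stats::quantile(.data$beta, 0.05),
    hi = stats::quantile(.data$beta, 0.95),
    .groups = "drop"
  )
  ggplot2::ggplot(s, ggplot2::aes(x = .data$method, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::geom_hline(yintercept = object$config$b1, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "estimated multivariable association (log odds)",
      title = sprintf("N_I = %d, N_L = %d, sigma_h = %g, rho = %g",
                      object$config$n_ipd, object$config$n_lit,
                      object$config$sigma_h, object$config$rho),
      subtitle = "mean and central 90% range across repetitions; dashed = truth"
    ) +
    ggplot2::theme_minimal()
}
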