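# shared fixtures and independent oracles, all built in code

# completely separated toy data: y = 1 exactly when x > 0
separated_toy <- function(n = 20) {
  x <- c(seq(-2, -0.1, length.out = n / 2), seq(0.1, 2, length.out = n / 2))
  tibble::tibble(y = as.integer(x > 0), x = x)
}

# dense 2-D grid search for the Cauchy-prior posterior mode of an
# intercept + one-slope logistic model on the RAW scale (no input
# standardization): coarse pass over [-10, 10]^2, then a fine local pass.
grid_map_oracle <- function(x, y, intercept_scale = 10, coefficient_scale = 2.5,
                            coarse = 0.05, fine = 0.002) {
  X <- cbind(1, x)
  lp <- function(G) {
    eta <- X %*% t(G) # n x nGrid
    ll <- colSums(y * eta - log1p(exp(eta)))
    ll + dcauchy(G[, 1], 0, intercept_scale, log = TRUE) +
      dcauchy(G[, 2], 0, coefficient_scale, log = TRUE)
  }
  g1 <- seq(-10, 10, by = coarse)
  G <- as.matrix(expand.grid(b0 = g1, b1 = g1))
  best <- G[which.max(lp(G)), ]
  g0 <- seq(best[1] - 1.5 * coarse, best[1] + 1.5 * coarse, by = fine)
  g1 <- seq(best[2] - 1.5 * coarse, best[2] + 1.5 * coarse, by = fine)
  G <- as.matrix(expand.grid(b0 = g0, b1 = g1))
  unname(G[which.max(lp(G)), ])
}

# minimal hand-built fit/pool/adaptation objects for arithmetic checks
fake_fit <- function(beta, variance, term = "x1") {
  co <- c("(Intercept)" = -3, beta)
  names(co)[2] <- term
  V <- diag(c(0.5, variance))
  dimnames(V) <- list(names(co), names(co))
  structure(
    list(coefficients = co, vcov = V, converged = TRUE, separation = FALSE,
         gradient_norm = NA_real_, method = "ml", prior = prior_none(),
         outcome = "y", predictors = term, n = 100L),
    class = "logistic_fit"
  )
}
fake_pool <- function(mu, variance) {
  structure(list(mu = mu, variance = variance, tau2 = 0, method = "random",
                 k = 5L), class = "pooled_estimate")
}
fake_adaptation <- function(mu_delta, sigma2_delta, prior = prior_none()) {
  structure(
    list(mu_delta = mu_delta, sigma2_delta = sigma2_delta,
         n_bootstrap = 200L, n_flagged = 0L, n_redrawn = 0L,
         exclude_flagged = FALSE, prior = prior, predictor = "x1",
         deltas = numeric(0)),
    class = "adaptation_dist"
  )
}

# hand-rolled DerSimonian-Laird pooling, the independent cross-check for
# pool_random()
dl_pool_oracle <- function(beta, v) {
  w <- 1 / v
  mu_f <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - mu_f)^2)
  k <- length(beta)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (v + tau2)
  list(mu = sum(ws * beta) / sum(ws), variance = 1 / sum(ws), tau2 = tau2)
}
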