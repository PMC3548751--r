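# the adaptation estimators: analytic (Greenland/Steyerberg) and
# bootstrap-based (improved); fake_* builders live in helper-uniadapt.R

test_that("the analytic adaptation reproduces the textbook arithmetic", {
  a <- gs_adapt(fake_pool(1.0, 0.03), fake_fit(0.9, 0.06),
                fake_fit(0.8, 0.05), "x1")
  expect_equal(a$beta, 0.9)
  expect_equal(a$variance, 0.03 + 0.05 - 0.06, tolerance = 1e-12)
  expect_false(a$negative_variance_flag)
  expect_equal(a$method, "GS")
})

test_that("a negative analytic variance is flagged, never clipped or NaN", {
  a <- gs_adapt(fake_pool(1.0, 0.005), fake_fit(0.9, 0.06),
                fake_fit(0.8, 0.05), "x1")
  expect_equal(a$variance, -0.005, tolerance = 1e-12)
  expect_true(a$negative_variance_flag)
  expect_false(is.nan(a$beta))
  td <- tidy(a)
  expect_true(is.na(td$conf.low))
})

test_that("zero literature weight reduces the adaptation to the IPD fit", {
  a <- gs_adapt(fake_pool(1.0, 0.03), fake_fit(0.9, 0.06),
                fake_fit(0.8, 0.05), "x1", c_weight = 0)
  expect_equal(a$beta, 0.8)
  expect_equal(a$variance, 0.05)
})

test_that("the improved adaptation is the exact sum of its two components", {
  a <- improved_adapt(fake_pool(1.0, 0.02), fake_adaptation(-0.2, 0.03))
  expect_equal(a$beta, 0.8)
  expect_equal(a$variance, 0.05, tolerance = 1e-12)

  null_ad <- improved_adapt(fake_pool(1.0, 0.02), fake_adaptation(0, 0))
  expect_equal(null_ad$beta, 1.0)
  expect_equal(null_ad$variance, 0.02)

  a2 <- improved_adapt(fake_pool(0.35, 0.03), fake_adaptation(0.05, 0.12))
  expect_equal(a2$beta, 0.40)
  expect_equal(a2$variance, 0.15, tolerance = 1e-12)

  # variance conservation under random component pairs (independence: no
  # hidden covariance term), and non-negativity by construction
  set.seed(4)
  for (i in 1:20) {
    pv <- runif(1, 0.001, 0.5); sv <- runif(1, 0, 0.5)
    a3 <- improved_adapt(fake_pool(rnorm(1), pv),
                         fake_adaptation(rnorm(1), sv))
    expect_equal(a3$variance, pv + sv, tolerance = 1e-12)
    expect_gte(a3$variance, 0)
    expect_false(a3$negative_variance_flag)
  }
})

test_that("GS and improved point estimates coincide in the no-resampling limit", {
  fu <- fake_fit(0.9, 0.06)
  fm <- fake_fit(0.8, 0.05)
  pool <- fake_pool(1.1, 0.02)
  delta_exact <- 0.8 - 0.9
  gs <- gs_adapt(pool, fu, fm, "x1")
  imp <- improved_adapt(pool, fake_adaptation(delta_exact, 0.04))
  expect_equal(gs$beta, imp$beta, tolerance = 1e-12)
})

test_that("the method label follows the adaptation's prior", {
  a_np <- improved_adapt(fake_pool(1, 0.02), fake_adaptation(0.1, 0.01))
  expect_equal(a_np$method, "improved_no_prior")
  a_wp <- improved_adapt(fake_pool(1, 0.02),
                         fake_adaptation(0.1, 0.01,
                                         prior_weakly_informative()))
  expect_equal(a_wp$method, "improved_weak_prior")
})

test_that("the bootstrap recovers the true univariable-to-multivariable shift", {
  # at scale, the shift is the gap between the adjusted coefficient (1.45)
  # and its marginal counterpart (about 1.25)
  d <- generate_ipd(scenario_config(n_ipd = 2e4, seed = 33))
  ad <- bootstrap_adaptation(d, "y", "x1", c("x1", "x2"),
                             prior = prior_weakly_informative(),
                             n_bootstrap = 100, seed = 1)
  expect_lt(abs(ad$mu_delta - 0.20), 0.06)
  expect_equal(ad$n_bootstrap, 100)
  expect_lte(ad$n_flagged, 100)
})

test_that("adjusting for a null covariate leaves the association unchanged", {
  d <- generate_ipd(scenario_config(n_ipd = 500, seed = 21))
  d$x2 <- 0
  ad <- bootstrap_adaptation(d, "y", "x1", c("x1", "x2"),
                             prior = prior_weakly_informative(),
                             n_bootstrap = 60, seed = 2)
  expect_equal(ad$mu_delta, 0, tolerance = 0.02)
})

test_that("without the prior, separation inflates the adaptation spread", {
  # small IPD with few events: resampled ML fits are frequently unstable
  d <- generate_ipd(scenario_config(n_ipd = 80, seed = 1203))
  none <- bootstrap_adaptation(d, "y", "x1", c("x1", "x2"),
                               prior = prior_none(),
                               n_bootstrap = 150, seed = 5)
  weak <- bootstrap_adaptation(d, "y", "x1", c("x1", "x2"),
                               prior = prior_weakly_informative(),
                               n_bootstrap = 150, seed = 5)
  expect_gt(none$n_flagged, 0)
  expect_gte(none$sigma2_delta, weak$sigma2_delta)
})

test_that("bootstrap preconditions are enforced", {
  d <- generate_ipd(scenario_config(n_ipd = 200, seed = 3))
  expect_error(
    bootstrap_adaptation(d, "y", "x3", c("x1", "x2"), n_bootstrap = 10),
    "must be one of"
  )
  expect_error(
    bootstrap_adaptation(d, "y", "x1", c("x1", "x2"), n_bootstrap = 1),
    "at least 2"
  )
  d1 <- tibble::tibble(y = c(1, rep(0, 30)), x1 = rnorm(31), x2 = rnorm(31))
  expect_error(
    bootstrap_adaptation(d1, "y", "x1", c("x1", "x2"), n_bootstrap = 10),
    "2 events"
  )
})

test_that("the Monte-Carlo error of mu_delta shrinks with more replicates", {
  d <- generate_ipd(scenario_config(n_ipd = 150, seed = 55))
  mu_at <- function(B, seeds) {
    vapply(seeds, function(s) {
      bootstrap_adaptation(d, "y", "x1", c("x1", "x2"),
                           prior = prior_weakly_informative(),
                           n_bootstrap = B, seed = s)$mu_delta
    }, numeric(1))
  }
  sd_small <- sd(mu_at(25, 1:12))
  sd_large <- sd(mu_at(400, 1:12))
  expect_lt(sd_large, sd_small)
})

test_that("the one-call driver returns a complete adapted row", {
  d <- generate_ipd(scenario_config(n_ipd = 300, seed = 17))
  lit <- univariable_estimates(c(1.2, 1.3, 1.15), c(0.05, 0.04, 0.06))
  for (m in c("gs", "improved-weak")) {
    row <- adapt_association(d, lit, "y", "x1", c("x1", "x2"),
                             method = m, n_bootstrap = 50, seed = 10)
    expect_equal(nrow(row), 1)
    expect_true(all(c("beta", "variance", "conf.low", "conf.high",
                      "pooled_mu", "tau2") %in% names(row)))
    expect_true(is.finite(row$beta))
  }
})
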