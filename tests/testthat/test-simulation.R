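# data generation from the reference model, metrics, and the scenario driver

test_that("generated IPD matches the reference-model construction", {
  cfg <- scenario_config(n_ipd = 1e5, seed = 1)
  d <- generate_ipd(cfg)
  expect_equal(nrow(d), 1e5)
  expect_true(all(d$y %in% c(0, 1)))
  expect_equal(mean(d$y), 0.09, tolerance = 0.05)
  expect_equal(cor(d$x1, d$x2), 0, tolerance = 0.02)
  expect_equal(sd(d$x1), 1, tolerance = 0.02)

  d5 <- generate_ipd(scenario_config(n_ipd = 1e5, rho = 0.5, seed = 2))
  expect_equal(cor(d5$x1, d5$x2), 0.5, tolerance = 0.02)
  expect_equal(sd(d5$x2), 1, tolerance = 0.02)
})

test_that("literature generation honours the heterogeneity setting", {
  hom <- generate_literature(scenario_config(sigma_h = 0, n_lit = 300,
                                             seed = 3))
  expect_equal(hom$b1_true, rep(1.45, 4))
  expect_equal(nrow(hom), 4)
  expect_true(all(hom$variance > 0))

  het <- generate_literature(scenario_config(sigma_h = 0.3, n_lit = 40,
                                             n_lit_studies = 200, seed = 4))
  expect_equal(sd(het$b1_true), 0.3, tolerance = 0.05)

  big <- generate_literature(scenario_config(sigma_h = 0, n_lit = 2e5,
                                             n_lit_studies = 1, seed = 5))
  expect_equal(big$beta, 1.25, tolerance = 0.03)
})

test_that("percentage bias is plain arithmetic on the estimate mean", {
  expect_equal(percentage_bias(rep(1.45, 5), 1.45), 0)
  expect_equal(percentage_bias(rep(1.595, 3), 1.45), 10, tolerance = 1e-10)
  expect_equal(percentage_bias(rep(1.3055, 3), 1.45), -9.9655,
               tolerance = 1e-3)
  expect_error(percentage_bias(c(1, 2), 0), "non-zero")
  expect_error(percentage_bias(numeric(0), 1), "non-empty")
})

test_that("mse is squared mean bias plus empirical (n-1) variance", {
  expect_equal(mse(rep(1.45, 3), 1.45), 0)
  expect_equal(mse(c(1.4, 1.5), 1.45), var(c(1.4, 1.5)), tolerance = 1e-12)
  expect_equal(mse(c(1.4, 1.5), 1.45), 0.005, tolerance = 1e-12)
  expect_equal(mse(rep(1.55, 4), 1.45), 0.01, tolerance = 1e-12)
  expect_error(mse(1.4, 1.45), "at least 2")
})

test_that("ci_coverage handles extreme and negative variances as documented", {
  expect_equal(as.numeric(ci_coverage(c(1, 2, 3), rep(1e12, 3), 1.45)), 1)
  expect_equal(as.numeric(ci_coverage(c(1, 2), c(0, 0), 1.45)), 0)
  cv <- ci_coverage(c(1.4, 1.5, 9), c(0.04, -0.01, 0.04), 1.45)
  expect_equal(attr(cv, "n_negative_variance"), 1L)
  expect_equal(as.numeric(cv), 0.5)
  expect_error(ci_coverage(1:3, 1:2, 1), "same length")
})

test_that("Wald intervals are calibrated under exact normality", {
  set.seed(100)
  n <- 1e5
  v <- 0.04
  est <- rnorm(n, 1.45, sqrt(v))
  cov <- as.numeric(ci_coverage(est, rep(v, n), 1.45, level = 0.9))
  expect_equal(cov, 0.90, tolerance = 0.005)
})

test_that("a scenario is bit-reproducible from its config and seed", {
  cfg <- scenario_config(n_ipd = 120, n_reps = 8, bootstrap_B = 25, seed = 77)
  r1 <- run_scenario(cfg)
  r2 <- run_scenario(cfg)
  expect_identical(r1$estimates, r2$estimates)
  expect_identical(r1$metrics, r2$metrics)
})

test_that("improved-method variances are never negative across repetitions", {
  cfg <- scenario_config(n_ipd = 100, n_reps = 30, bootstrap_B = 40,
                         seed = 13)
  res <- run_scenario(cfg, methods = c("improved_no_prior",
                                       "improved_weak_prior"))
  ok <- !res$estimates$failed
  expect_true(all(res$estimates$variance[ok] >= 0))
  expect_equal(res$metrics$n_negative_variance, c(0L, 0L))
})

test_that("the IPD-only route never touches pooling or literature generation", {
  testthat::local_mocked_bindings(
    generate_literature = function(...) stop("literature must not be generated"),
    pool_random = function(...) stop("pooling must not be invoked"),
    .package = "uniadapt"
  )
  cfg <- scenario_config(n_ipd = 150, n_reps = 5, seed = 6)
  res <- run_scenario(cfg, methods = "no_meta")
  expect_equal(nrow(res$metrics), 1)
  expect_true(all(is.na(res$estimates$n_boot_flagged)))
})

test_that("no-meta MSE decreases as the IPD grows", {
  mse_at <- function(n, seed) {
    res <- run_scenario(scenario_config(n_ipd = n, n_reps = 300, seed = seed),
                        methods = "no_meta")
    res$metrics$mse
  }
  m <- c(mse_at(100, 41), mse_at(500, 42), mse_at(1000, 43))
  expect_true(all(diff(m) < 0))
})

test_that("scenario metrics carry effective repetition counts and flags", {
  cfg <- scenario_config(n_ipd = 100, n_reps = 40, seed = 19)
  res <- run_scenario(cfg, methods = c("no_meta", "gs"))
  m <- res$metrics
  expect_equal(m$method, c("no_meta", "gs"))
  expect_true(all(m$n_reps_effective <= 40))
  expect_true(all(m$n_negative_variance >= 0))
  td <- tidy(res)
  expect_true(all(c("n_ipd", "n_lit", "sigma_h", "rho", "pb", "mse",
                    "coverage") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$seed, 19L)
})

test_that("invalid scenario settings are rejected", {
  expect_error(scenario_config(n_ipd = 0), "positive")
  expect_error(scenario_config(sigma_h = -0.1), "non-negative")
  expect_error(scenario_config(rho = 1), "strictly between")
  expect_error(scenario_config(ci_level = 1.1), "in \\(0, 1\\)")
})

test_that("autoplot produces ggplot objects for both result types", {
  d <- generate_ipd(scenario_config(n_ipd = 200, seed = 23))
  ad <- bootstrap_adaptation(d, "y", "x1", c("x1", "x2"),
                             n_bootstrap = 30, seed = 1)
  expect_s3_class(autoplot(ad), "ggplot")
  res <- run_scenario(scenario_config(n_ipd = 150, n_reps = 6, seed = 2),
                      methods = c("no_meta", "gs"))
  expect_s3_class(autoplot(res), "ggplot")
})
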