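test_that("simulation refuses uncalibrated parameters unless overridden", {
  params <- reference_logit_params("one_way_urban")
  params$intercept <- -4.8
  cfg <- simulation_config(params, baseline_carbon_ar(), runs = 5,
                           horizon = 20, seed = 1)
  expect_error(simulate_incidence(cfg), "calibration")
  cfg$allow_uncalibrated <- TRUE
  expect_s3_class(simulate_incidence(cfg), "simulation_summary")
})

test_that("degenerate shocks give a constant path at the certainty equivalent", {
  params <- calibrated_baseline()
  ar0 <- retarget_ar(baseline_carbon_ar(), target_sd = 0)
  s <- simulate_incidence(simulation_config(params, ar0, runs = 10,
                                            horizon = 100, seed = 1,
                                            keep_paths = TRUE))
  expect_equal(unique(as.numeric(s$trajectories)), 0.062, tolerance = 1e-12)
  expect_equal(s$expected_mean, s$mu_p_bar, tolerance = 1e-12)
  expect_equal(s$expected_wedge, 0, tolerance = 1e-12)
  expect_equal(expected_wedge(s)$value, 0, tolerance = 1e-12)
})

test_that("simulated mean matches a Gaussian quadrature oracle (iid carbon)", {
  # order-0 carbon (iid Gaussian growth), single lag, no persistence: the
  # expected incidence is a one-dimensional integral
  params <- logit_params(lag_coeffs = 1.3)
  pt <- transfer_point(1.624)
  params <- calibrate_params(params, pt, 0.062)
  car <- ar_fit(1.624, numeric(0), 0.68)
  s <- simulate_incidence(simulation_config(params, car, runs = 400,
                                            horizon = 2000, seed = 5))
  oracle <- quad_expected_logistic(params$intercept, 1.3, 1.624, 0.68)
  expect_equal(s$expected_mean, oracle, tolerance = 0.005)
  expect_gt(s$expected_wedge, 0)
})

test_that("runs are reproducible under a seed and consistent across seeds", {
  params <- calibrated_baseline()
  car <- baseline_carbon_ar()
  s1 <- simulate_incidence(simulation_config(params, car, runs = 100,
                                             horizon = 300, seed = 7))
  s2 <- simulate_incidence(simulation_config(params, car, runs = 100,
                                             horizon = 300, seed = 7))
  expect_identical(s1$per_run, s2$per_run)
  s3 <- simulate_incidence(simulation_config(params, car, runs = 100,
                                             horizon = 300, seed = 8))
  # different seeds: cross-run mean CIs overlap
  expect_lt(max(s1$ci["mean", 1], s3$ci["mean", 1]),
            min(s1$ci["mean", 2], s3$ci["mean", 2]))
  # CI lower <= upper for every statistic
  expect_true(all(s1$ci[, 1] <= s1$ci[, 2]))
  # wedge identity: mean of per-run means minus certainty equivalent
  expect_equal(s1$expected_wedge, mean(s1$per_run$mean) - s1$mu_p_bar,
               tolerance = 1e-12)
})

test_that("simulated wedge agrees with the delta-method oracle at baseline", {
  params <- calibrated_baseline()
  car <- baseline_carbon_ar()
  s <- simulate_incidence(simulation_config(params, car, runs = 1000,
                                            horizon = 2000, seed = 11))
  # second-order Taylor: E[UW] ~ 0.5 p(1-p)(1-2p) Var(sum_j h_j c_{t-j}),
  # Var from the Yule-Walker autocorrelations
  h <- params$lag_coeffs
  r <- ar_acf(car$coefficients, length(h) - 1)
  Rm <- outer(seq_along(h), seq_along(h), function(i, j) r[abs(i - j) + 1])
  vx <- car$implied_sd^2 * drop(t(h) %*% Rm %*% h)
  p <- s$mu_p_bar
  oracle <- 0.5 * p * (1 - p) * (1 - 2 * p) * vx
  expect_equal(s$expected_wedge, oracle, tolerance = 0.25)
})

test_that("Bernoulli-state dynamic is available and near the smooth recursion", {
  params <- calibrated_baseline()
  car <- baseline_carbon_ar()
  sb <- simulate_incidence(simulation_config(params, car, runs = 300,
                                             horizon = 1000, seed = 3,
                                             dynamic = "state"))
  sp <- simulate_incidence(simulation_config(params, car, runs = 300,
                                             horizon = 1000, seed = 3))
  expect_equal(sb$expected_mean, sp$expected_mean, tolerance = 0.05)
})

test_that("beta benchmark: moment matching, ML, round-trip and errors", {
  u <- fit_beta_benchmark(0.5, sqrt(1 / 12))
  expect_equal(u$alpha, 1, tolerance = 1e-10)
  expect_equal(u$beta, 1, tolerance = 1e-10)

  b <- fit_beta_benchmark(0.062, 0.056)
  expect_equal(b$alpha, 1.088, tolerance = 1e-3)
  expect_equal(b$beta, 16.46, tolerance = 1e-3)
  expect_equal(b$mean, 0.062, tolerance = 1e-10)
  expect_equal(b$sd, 0.056, tolerance = 1e-10)
  expect_equal(b$alpha * b$beta / ((b$alpha + b$beta)^2 * (b$alpha + b$beta + 1)),
               0.056^2, tolerance = 1e-10)

  expect_error(fit_beta_benchmark(0.062, 0.25), "too large")
  expect_error(fit_beta_benchmark(1.2, 0.1), "\\(0, 1\\)")

  set.seed(17)
  x <- rbeta(5000, 1.088, 16.46)
  bm <- fit_beta_benchmark(data = x, method = "ml")
  expect_equal(bm$alpha, 1.088, tolerance = 0.08)
  expect_equal(bm$beta, 16.46, tolerance = 0.08)
})

test_that("RMSE vs beta benchmark: self-limit, quadrature oracle, seeding", {
  b <- fit_beta_benchmark(0.062, 0.056)
  set.seed(23)
  self <- matrix(rbeta(2000 * 50, b$alpha, b$beta), 2000, 50)
  expect_lte(rmse_vs_beta(self, b, seed = 1), 0.01)

  # constant trajectory at the beta mean: sorted-sample RMSE converges to
  # the beta's standard deviation (quadrature of (q(u) - m)^2 = variance)
  const <- matrix(b$mean, 2000, 20)
  expect_equal(rmse_vs_beta(const, b, seed = 2), b$sd, tolerance = 0.03)

  expect_identical(rmse_vs_beta(self, b, seed = 9),
                   rmse_vs_beta(self, b, seed = 9))
})

test_that("convexity percentile runs: ordering, zero covariance, wedge sign", {
  params <- calibrated_baseline()
  car <- baseline_carbon_ar()
  cfg <- simulation_config(params, car, runs = 200, horizon = 500, seed = 13)
  k <- params$lag_order + 2
  se <- c(0.15, 0.1, 0.1, 0.12)
  Vnames <- c("(Intercept)", paste0("c_lag", 0:3))
  V <- diag(c(0.2, se^2)); dimnames(V) <- list(Vnames, Vnames)
  fake_fit <- list(params = params, covariance = V)

  lo <- convexity_percentile_run(fake_fit, 2.5, cfg)
  hi <- convexity_percentile_run(fake_fit, 97.5, cfg)
  base <- simulate_incidence(cfg)
  expect_gt(hi$expected_mean, lo$expected_mean)
  expect_gt(lo$expected_wedge, 0)
  expect_gt(hi$expected_wedge, 0)
  # both recalibrate to the same certainty equivalent
  expect_equal(lo$mu_p_bar, 0.062, tolerance = 1e-12)
  expect_equal(hi$mu_p_bar, 0.062, tolerance = 1e-12)

  V0 <- V * 0
  fake0 <- list(params = params, covariance = V0)
  same <- convexity_percentile_run(fake0, 97.5, cfg)
  expect_equal(same$expected_mean, base$expected_mean, tolerance = 1e-12)

  expect_error(convexity_percentile_run(fake_fit, 50, cfg), "2.5 or 97.5")
})
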