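test_that("disaster_panel validates and collapses events to a binary state", {
  p <- disaster_panel(c("A", "A", "B"), c(2000, 2001, 2000),
                      events = c(0, 3, 1), urban_share = c(0.5, 0.5, 0.7))
  expect_equal(p$event, c(0L, 1L, 1L))
  expect_true(all(p$events >= p$event))
  expect_error(
    disaster_panel(c("A", "A"), c(2000, 2000), c(0, 1), c(0.5, 0.5)),
    "duplicate")
  expect_error(
    disaster_panel("A", 2000, 1, 1.5), "urban_share")
  expect_error(
    disaster_panel("A", 2000, -1, 0.5), "non-negative")
})

test_that("build_design lag bookkeeping and coverage checks", {
  years <- 1960:2022
  set.seed(42)
  pat <- list(A = rbinom(63, 1, 0.3), B = rbinom(63, 1, 0.3))
  pan <- toy_panel(pat, years)
  carbon <- toy_carbon(1956:2022)
  d <- build_design(pan, carbon, P = 3, fe = "none")

  # outcome years 1964-2022, regressors dated 1963-2021 with lags to 1960
  expect_equal(range(d$data$year), c(1964, 2022))
  expect_equal(nrow(d$data), 2 * 59)
  expect_equal(d$data$c_lag0,
               carbon$growth[match(d$data$year - 1, carbon$years)])
  expect_equal(d$data$c_lag3,
               carbon$growth[match(d$data$year - 4, carbon$years)])

  # carbon that stops short of the needed lags errors
  expect_error(build_design(pan, toy_carbon(1962:2022), P = 3), "cover")
  expect_error(build_design(pan, carbon, P = -1), ">= 0")
})

test_that("two-way FE adds (n_countries - 1) + (n_years - 1) dummies", {
  years <- 1990:2010
  set.seed(1)
  pat <- list(A = rbinom(21, 1, 0.5), B = rbinom(21, 1, 0.5),
              C = rbinom(21, 1, 0.5), D = rbinom(21, 1, 0.5))
  pan <- toy_panel(pat, years)
  carbon <- toy_carbon(1985:2010, values = rnorm(26, 1.6, 0.7))
  d <- build_design(pan, carbon, P = 3, fe = "two_way")
  expect_length(d$degenerate_countries, 0)
  fit <- fit_panel_logit(d)
  # degenerate years (all countries same outcome) are dropped before fitting
  kept_years <- setdiff(unique(d$data$year), as.integer(d$degenerate_years))
  mm <- model.matrix(fit$glm)
  # intercept + 4 lags + log_urban + lag_state + dummy coding
  expect_equal(ncol(mm), 1 + 4 + 1 + 1 + (4 - 1) + (length(kept_years) - 1))
  # global carbon lags lie in the year-dummy span, so some dummies are
  # aliased - but the carbon terms themselves stay identified
  expect_lt(length(fit$coefficients), ncol(mm))
  expect_true(all(is.finite(fit$params$lag_coeffs)))
})

test_that("degenerate countries are excluded under one-way FE", {
  years <- 1990:2014
  set.seed(2)
  pat <- list(A = rbinom(25, 1, 0.5), B = rbinom(25, 1, 0.5),
              C = rbinom(25, 1, 0.5), D = rbinom(25, 1, 0.5),
              Z = rep(0L, 25))  # never any events
  pan <- toy_panel(pat, years)
  carbon <- toy_carbon(1985:2014)
  d <- build_design(pan, carbon, P = 3, fe = "one_way")
  expect_true("Z" %in% d$degenerate_countries)
  fit <- fit_panel_logit(d)
  expect_equal(fit$n_obs, 4 * 21)  # Z's 21 outcome rows dropped
  expect_error(fit_panel_logit(d, drop_degenerate = FALSE),
               "perfect separation.*Z")

  # all-zero outcomes: single class -> separation error
  pan0 <- toy_panel(list(A = rep(0L, 25), B = rep(0L, 25)), years)
  d0 <- build_design(pan0, carbon, P = 3, fe = "none")
  expect_error(fit_panel_logit(d0), "single-class|separation")
})

test_that("no-FE fit equals plain logistic regression on the same rows", {
  years <- 1980:2019
  set.seed(3)
  pan <- toy_panel(list(A = rbinom(40, 1, 0.4)), years,
                   urban = plogis(seq(-1, 1, length.out = 40)))
  carbon <- toy_carbon(1975:2019, values = rnorm(45, 1.6, 0.7))
  d <- build_design(pan, carbon, P = 2, fe = "none")
  fit <- fit_panel_logit(d)
  ref <- glm(y ~ c_lag0 + c_lag1 + c_lag2 + log_urban + lag_state,
             family = binomial(), data = d$data)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(fit$n_obs, nrow(d$data))
})

test_that("estimates invariant to row order and country relabeling", {
  spec <- panel_generator_spec(n_countries = 30, years = 1990:2022, seed = 8)
  pan <- generate_panel(spec)
  carbon <- attr(pan, "carbon")
  d1 <- build_design(pan, carbon, fe = "one_way")
  f1 <- fit_panel_logit(d1)

  shuffled <- pan[sample(nrow(pan)), ]
  pan2 <- disaster_panel(shuffled$country, shuffled$year, shuffled$events,
                         shuffled$urban_share)
  f2 <- fit_panel_logit(build_design(pan2, carbon, fe = "one_way"))
  expect_equal(f1$params$lag_coeffs, f2$params$lag_coeffs, tolerance = 1e-8)

  relabeled <- disaster_panel(paste0("X", pan$country), pan$year, pan$events,
                              pan$urban_share)
  f3 <- fit_panel_logit(build_design(relabeled, carbon, fe = "one_way"))
  expect_equal(f1$params$lag_coeffs, f3$params$lag_coeffs, tolerance = 1e-8)
  expect_equal(f1$auroc, f3$auroc, tolerance = 1e-12)
})

test_that("AUROC: examples, errors, and brute-force pair-counting oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auroc(c(0.1, 0.9), c(1, 1)), "undefined")

  set.seed(99)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))     # ensure both classes
    s <- round(runif(n), sample(1:3, 1))    # discretise to create ties
    expect_equal(auroc(s, y), auroc_bruteforce(s, y), tolerance = 1e-12)
  }
})

test_that("McFadden pseudo R2: limits and hand-computed toy", {
  expect_equal(pseudo_r2(-10, -10), 0)
  expect_error(pseudo_r2(-5, 0), "zero")

  # 4-row toy, enumerate Bernoulli likelihoods by hand
  y <- c(1, 0, 1, 0)
  p_hat <- c(0.8, 0.3, 0.6, 0.4)
  ll <- sum(y * log(p_hat) + (1 - y) * log(1 - p_hat))
  ll0 <- sum(y * log(0.5) + (1 - y) * log(0.5))
  expect_equal(pseudo_r2(ll, ll0),
               1 - ll / (4 * log(0.5)), tolerance = 1e-12)
  expect_gt(pseudo_r2(ll, ll0), 0)
  expect_lt(pseudo_r2(ll, ll0), 1)

  # near-saturated fit on separable data approaches 1
  expect_gt(pseudo_r2(-1e-6, log(0.5) * 4), 0.99)
})

test_that("sign recovery on a small synthetic panel (smoke-scale)", {
  spec <- panel_generator_spec(n_countries = 120, years = 1980:2022, seed = 31)
  pan <- generate_panel(spec)
  fit <- fit_panel_logit(build_design(pan, attr(pan, "carbon"), fe = "one_way"))
  expect_true(fit$converged)
  expect_true(all(fit$params$lag_coeffs > 0))
  expect_gt(fit$auroc, 0.6)
  expect_gt(fit$params$control_coeffs[[1]], 0)
  # cluster-robust covariance is positive definite with matching dimension
  fr <- fit_panel_logit(build_design(pan, attr(pan, "carbon"), fe = "none"),
                        cluster_robust = TRUE)
  expect_equal(dim(fr$covariance), rep(length(fr$coefficients), 2))
  expect_true(all(diag(fr$covariance) > 0))
})
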