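# Monte-Carlo engine: pushes simulated AR carbon paths through the logistic
# transfer, summarises per-run incidence statistics, the uncertainty wedge,
# and the beta-distribution benchmark RMSE.

#' Simulation configuration
#'
#' @param params a calibrated [logit_params()] (see [calibrate_params()]).
#' @param carbon a stationary [ar_fit()] driving CO2 growth.
#' @param runs number of Monte-Carlo runs (default 2000).
#' @param horizon years per run (default 2000).
#' @param burn_in discarded warm-up years for the carbon process.
#' @param shocks a [shock_spec()]; its seed is superseded by `seed`.
#' @param seed integer seed for the whole simulation.
#' @param dynamic how the persistence term enters the recursion:
#'   `"probability"` multiplies the previous period's simulated probability
#'   (deterministic recursion, smooth trajectories); `"state"` draws a
#'   Bernoulli state each period; `"fixed"` holds the term at the
#'   calibration-point lagged incidence (used in scenario evaluation, where
#'   every non-carbon term is frozen at its calibration value).
#' @param keep_paths retain the full incidence trajectory matrix (horizon x
#'   runs); needed for [rmse_vs_beta()].
#' @param allow_uncalibrated permit parameters without a calibration stamp.
#' @return an object of class `"simulation_config"`.
#' @export
simulation_config <- function(params, carbon, runs = 2000, horizon = 2000,
                              burn_in = 500,
                              shocks = shock_spec("gaussian"), seed = 1,
                              dynamic = c("probability", "state", "fixed"),
                              keep_paths = FALSE,
                              allow_uncalibrated = FALSE) {
  dynamic <- match.arg(dynamic)
  stopifnot(runs >= 1, horizon >= 1, inherits(params, "logit_params"),
            inherits(carbon, "ar_fit"))
  structure(list(params = params, carbon = carbon, runs = runs,
                 horizon = horizon, burn_in = burn_in, shocks = shocks,
                 seed = seed, dynamic = dynamic, keep_paths = keep_paths,
                 allow_uncalibrated = allow_uncalibrated),
            class = "simulation_config")
}

#' Simulate stochastic disaster incidence
#'
#' For each run, simulates an AR carbon growth path, forms the log-odds
#' \eqn{x_t = \bar h + \sum_j h_j c_{t-j} + \sum_k \gamma_k \mu_k +
#' \delta\,(\mathrm{lagged\ term})} with the controls held fixed at their
#' calibration means, and maps it through the logistic transfer,
#' \eqn{\tilde p_{t+1} = \Lambda(x_t)}. Reports per-run mean, sd, skewness
#' and kurtosis with cross-run 95 percent percentile intervals, and the
#' expected uncertainty wedge \eqn{E[\tilde\mu_p] - \bar\mu_p}.
#'
#' @param config a [simulation_config()]. The parameters must carry a
#'   calibration stamp unless `allow_uncalibrated = TRUE`.
#' @return an object of class `"simulation_summary"`: list with `per_run`
#'   (data frame of per-run statistics), `ci` (2.5/97.5 percentile bounds per
#'   statistic), `expected_mean`, `mu_p_bar`, `expected_wedge`, `wedge_ci`
#'   (all probabilities as fractions), `runs`, `horizon`, `seed`, and
#'   `trajectories` (horizon x runs matrix) when `keep_paths` is set.
#' @export
simulate_incidence <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  params <- config$params
  calib <- attr(params, "calibration")
  if (is.null(calib)) {
    if (!config$allow_uncalibrated) {
      stop_invalid("parameters carry no calibration stamp; calibrate with ",
                   "calibrate_params() or set allow_uncalibrated = TRUE")
    }
    calib <- list(
      point = transfer_point(
        config$carbon$implied_mean,
        covariate_means = rep(0, length(params$control_coeffs))),
      target = NA_real_)
  }
  point <- calib$point
  P <- params$lag_order
  Tn <- config$horizon
  R <- config$runs
  h <- params$lag_coeffs
  mu_p_bar <- certainty_equivalent(params, point)

  shocks <- config$shocks
  shocks$seed <- config$seed
  # simulate T + P growth values per run so every incidence date has P lags
  C <- simulate_carbon_paths(config$carbon, shocks, T = Tn + P,
                             burn_in = config$burn_in, R = R)
  xc <- matrix(0, Tn, R)
  for (j in 0:P) {
    xc <- xc + h[j + 1] * C[(P - j + 1):(P - j + Tn), , drop = FALSE]
  }
  base <- params$intercept + point$fe_mean +
    (if (length(params$control_coeffs)) {
      sum(params$control_coeffs * point$covariate_means)
    } else 0)

  delta <- params$persistence
  p <- matrix(0, Tn, R)
  if (config$dynamic == "fixed") {
    lagterm <- delta * point$p_bar
    for (t in seq_len(Tn)) {
      p[t, ] <- logistic_transfer(base + xc[t, ] + lagterm)
    }
  } else {
    prev <- rep(mu_p_bar, R)
    if (config$dynamic == "state") {
      prev <- rbinom(R, 1, mu_p_bar)
    }
    for (t in seq_len(Tn)) {
      p[t, ] <- logistic_transfer(base + xc[t, ] + delta * prev)
      prev <- if (config$dynamic == "state") rbinom(R, 1, p[t, ]) else p[t, ]
    }
  }

  m <- colMeans(p)
  pc <- p - rep(m, each = Tn)
  v <- colMeans(pc^2)
  sdv <- sqrt(v)
  skw <- ifelse(v > 0, colMeans(pc^3) / v^1.5, 0)
  krt <- ifelse(v > 0, colMeans(pc^4) / v^2, 0)
  per_run <- data.frame(mean = m, sd = sdv, skewness = skw, kurtosis = krt)
  ci <- t(vapply(per_run, quantile, numeric(2), probs = c(0.025, 0.975),
                 names = FALSE))
  colnames(ci) <- c("lower", "upper")
  expected_mean <- mean(m)
  structure(
    list(per_run = per_run,
         ci = ci,
         expected_mean = expected_mean,
         mu_p_bar = mu_p_bar,
         expected_wedge = uncertainty_wedge(expected_mean, mu_p_bar),
         wedge_ci = ci["mean", ] - mu_p_bar,
         runs = R, horizon = Tn, seed = config$seed,
         dynamic = config$dynamic,
         shock_family = config$shocks$family,
         trajectories = if (config$keep_paths) p else NULL),
    class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat("Simulated disaster incidence:", x$runs, "runs x", x$horizon,
      "years (", x$shock_family, "shocks )\n")
  cat(sprintf("  certainty equivalent  : %.2f %%\n", 100 * x$mu_p_bar))
  cat(sprintf("  mean E[mu_p]          : %.2f %%  95%% CI [%.1f, %.1f]\n",
              100 * x$expected_mean, 100 * x$ci["mean", 1],
              100 * x$ci["mean", 2]))
  cat(sprintf("  uncertainty wedge     : %.2f %%  95%% CI [%.1f, %.1f]\n",
              100 * x$expected_wedge, 100 * x$wedge_ci[1],
              100 * x$wedge_ci[2]))
  cat(sprintf("  sd / skew / kurt CIs  : [%.1f, %.1f] %% / [%.1f, %.1f] / [%.1f, %.1f]\n",
              100 * x$ci["sd", 1], 100 * x$ci["sd", 2],
              x$ci["skewness", 1], x$ci["skewness", 2],
              x$ci["kurtosis", 1], x$ci["kurtosis", 2]))
  invisible(x)
}

#' Expected uncertainty wedge with confidence interval
#'
#' \eqn{E[\tilde\mu_p] - \bar\mu_p}, with the cross-run CI endpoints of the
#' mean shifted by the certainty equivalent.
#'
#' @param summary a [simulate_incidence()] result.
#' @return list with `value` and `ci` (fractions).
#' @export
expected_wedge <- function(summary) {
  stopifnot(inherits(summary, "simulation_summary"))
  list(value = summary$expected_wedge, ci = summary$wedge_ci)
}

#' Beta benchmark for the incidence distribution
#'
#' Calibrates a beta distribution to the historical incidence record, by
#' default through moment matching:
#' \eqn{\alpha = m(m(1-m)/v - 1)}, \eqn{\beta = (1-m)(m(1-m)/v - 1)}.
#' Maximum-likelihood fitting is available when raw incidence data are
#' supplied.
#'
#' @param mean target mean, probability in (0, 1).
#' @param sd target standard deviation; must satisfy `sd^2 < mean*(1-mean)`.
#' @param data optional raw incidence sample in (0, 1) for ML fitting.
#' @param method `"moments"` (default) or `"ml"`.
#' @return an object of class `"beta_benchmark"` with `alpha`, `beta`,
#'   `mean`, `sd`.
#' @export
fit_beta_benchmark <- function(mean = NULL, sd = NULL, data = NULL,
                               method = c("moments", "ml")) {
  method <- match.arg(method)
  if (method == "moments") {
    check_finite_scalar(mean, "mean")
    check_finite_scalar(sd, "sd")
    if (mean <= 0 || mean >= 1) stop_invalid("`mean` must be in (0, 1)")
    v <- sd^2
    if (v <= 0 || v >= mean * (1 - mean)) {
      stop_invalid("variance too large for a beta distribution: need ",
                   "sd^2 < mean * (1 - mean)")
    }
    s <- mean * (1 - mean) / v - 1
    alpha <- mean * s
    beta <- (1 - mean) * s
  } else {
    stopifnot(!is.null(data), all(data > 0 & data < 1))
    nll <- function(par) -sum(stats::dbeta(data, exp(par[1]), exp(par[2]),
                                           log = TRUE))
    m0 <- mean(data); v0 <- var(data)
    s0 <- max(m0 * (1 - m0) / v0 - 1, 0.5)
    opt <- stats::optim(log(c(m0 * s0, (1 - m0) * s0)), nll)
    alpha <- exp(opt$par[1]); beta <- exp(opt$par[2])
  }
  structure(list(alpha = alpha, beta = beta,
                 mean = alpha / (alpha + beta),
                 sd = sqrt(alpha * beta / ((alpha + beta)^2 * (alpha + beta + 1)))),
            class = "beta_benchmark")
}

#' @export
print.beta_benchmark <- function(x, ...) {
  cat(sprintf("Beta benchmark: alpha = %.4f, beta = %.4f (mean %.4f, sd %.4f)\n",
              x$alpha, x$beta, x$mean, x$sd))
  invisible(x)
}

#' RMSE of simulated incidence against the beta benchmark
#'
#' For each run, draws an iid beta sample of equal length, sorts both the
#' simulated trajectory and the benchmark sample, and computes the
#' root-mean-square difference of the order statistics (quantile matching).
#' Reports the cross-run mean.
#'
#' @param trajectories horizon x runs matrix of simulated incidence (e.g.
#'   `summary$trajectories` with `keep_paths = TRUE`).
#' @param benchmark a [fit_beta_benchmark()].
#' @param seed integer seed for the benchmark draws.
#' @return scalar RMSE.
#' @export
rmse_vs_beta <- function(trajectories, benchmark, seed = 1) {
  stopifnot(is.matrix(trajectories), inherits(benchmark, "beta_benchmark"))
  set.seed(seed)
  Tn <- nrow(trajectories)
  rmse <- apply(trajectories, 2, function(col) {
    b <- sort(rbeta(Tn, benchmark$alpha, benchmark$beta))
    sqrt(mean((sort(col) - b)^2))
  })
  mean(rmse)
}

#' Re-run the simulation at a convexity percentile of the elasticities
#'
#' Replaces each lag coefficient by the 2.5th (weak convexity) or 97.5th
#' (strong convexity) endpoint of its normal-approximation confidence
#' interval, re-calibrates the intercept to the original incidence target at
#' the original point, and repeats the simulation.
#'
#' @param fit a [fit_panel_logit()] result (or any list with `params` and
#'   `covariance` whose first `P + 1` diagonal entries, after the intercept,
#'   correspond to the lag coefficients).
#' @param percentile 2.5 or 97.5 (only these two are supported).
#' @param config a [simulation_config()]; its `params` supply the
#'   calibration point and target.
#' @return a [simulate_incidence()] summary.
#' @export
convexity_percentile_run <- function(fit, percentile, config) {
  if (!percentile %in% c(2.5, 97.5)) {
    stop_invalid("`percentile` must be 2.5 or 97.5")
  }
  calib <- attr(config$params, "calibration")
  if (is.null(calib)) {
    stop_invalid("config parameters must be calibrated (calibrate_params())")
  }
  P <- fit$params$lag_order
  lag_names <- paste0("c_lag", 0:P)
  se <- if (all(lag_names %in% colnames(fit$covariance))) {
    sqrt(diag(fit$covariance)[lag_names])
  } else {
    sqrt(diag(fit$covariance)[seq_len(P + 1) + 1])  # after intercept
  }
  z <- qnorm(percentile / 100)
  shifted <- logit_params(
    lag_coeffs = fit$params$lag_coeffs + z * as.numeric(se),
    control_coeffs = config$params$control_coeffs,
    persistence = config$params$persistence)
  shifted <- calibrate_params(shifted, calib$point, calib$target)
  cfg <- config
  cfg$params <- shifted
  simulate_incidence(cfg)
}
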