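# Stationary AR(p) dynamics of annual CO2 concentration growth:
# estimation, Yule-Walker closed-form moments, seeded simulation, and
# bootstrap calibration checks.

#' Annual CO2 concentration series
#'
#' Holds annual CO2 concentration levels (ppm, optional) and/or percent
#' growth rates. When only levels are supplied, growth is derived as
#' `100 * diff(log(levels))`, so the growth track is one observation shorter
#' than the level track and is indexed by the later year of each pair.
#'
#' @param years strictly increasing, annually spaced calendar years.
#' @param growth annual growth rates, percent p.a. (same length as `years`),
#'   or `NULL` to derive from `levels`.
#' @param levels concentration levels in ppm (same length as `years`), or
#'   `NULL`.
#' @return an object of class `"carbon_series"` with elements `years`,
#'   `growth` (percent p.a.) and optionally `levels` / `level_years`.
#' @export
carbon_series <- function(years, growth = NULL, levels = NULL) {
  stopifnot(is.numeric(years), length(years) >= 2)
  if (any(diff(years) != 1)) {
    stop_invalid("`years` must be strictly increasing with annual spacing")
  }
  if (is.null(growth)) {
    if (is.null(levels)) stop_invalid("supply `growth` or `levels`")
    if (length(levels) != length(years)) {
      stop_invalid("`levels` must have one entry per year")
    }
    if (any(levels <= 0)) stop_invalid("ppm levels must be positive")
    out <- list(years = years[-1], growth = 100 * diff(log(levels)),
                levels = levels, level_years = years)
  } else {
    if (length(growth) != length(years)) {
      stop_invalid("`growth` must have one entry per year")
    }
    out <- list(years = years, growth = as.numeric(growth))
    if (!is.null(levels)) {
      if (length(levels) != length(years)) {
        stop_invalid("`levels` must have one entry per year")
      }
      out$levels <- levels
      out$level_years <- years
    }
  }
  structure(out, class = "carbon_series")
}

#' @export
print.carbon_series <- function(x, ...) {
  cat("Annual CO2 growth series:", length(x$growth), "obs,",
      min(x$years), "-", max(x$years), "\n")
  cat(sprintf("  mean %.3f %% p.a., sd %.3f %% p.a.\n",
              mean(x$growth), sd(x$growth)))
  invisible(x)
}

#' Construct an AR(p) model object directly
#'
#' Builds the autoregressive model
#' \deqn{c_t = \rho_0 + \sum_{j=1}^P \rho_j c_{t-j} + \xi_t}
#' from known coefficients (e.g. a published calibration), computing implied
#' stationary moments and checking stationarity via the companion-matrix
#' eigenvalues.
#'
#' @param intercept \eqn{\rho_0}.
#' @param coefficients \eqn{\rho_1 .. \rho_P}.
#' @param innovation_sd innovation standard deviation \eqn{\sigma_\xi},
#'   percent p.a.
#' @param diagnostics optional list of fit diagnostics.
#' @param nobs optional number of observations used in estimation.
#' @return an object of class `"ar_fit"`.
#' @export
ar_fit <- function(intercept, coefficients, innovation_sd,
                   diagnostics = list(), nobs = NA_integer_) {
  check_finite_scalar(intercept, "intercept")
  stopifnot(is.numeric(coefficients), all(is.finite(coefficients)),
            is.numeric(innovation_sd), innovation_sd >= 0)
  fit <- structure(
    list(order = length(coefficients),
         intercept = intercept,
         coefficients = as.numeric(coefficients),
         innovation_sd = innovation_sd,
         stationary = is_stationary_ar(coefficients),
         diagnostics = diagnostics,
         nobs = nobs),
    class = "ar_fit")
  if (fit$stationary) {
    mom <- stationary_moments(fit)
    fit$implied_mean <- mom[["mean"]]
    fit$implied_sd <- mom[["sd"]]
  } else {
    warning("AR coefficients are not stationary; implied moments undefined",
            call. = FALSE)
    fit$implied_mean <- NA_real_
    fit$implied_sd <- NA_real_
  }
  fit
}

#' @export
print.ar_fit <- function(x, ...) {
  cat("AR(", x$order, ") model for annual CO2 growth\n", sep = "")
  cat("  rho_0 =", format(x$intercept),
      " rho_j =", paste(format(x$coefficients), collapse = ", "), "\n")
  cat("  sigma_xi =", format(x$innovation_sd),
      " stationary:", x$stationary, "\n")
  if (x$stationary) {
    cat(sprintf("  implied mean %.4f, sd %.4f (%% p.a.)\n",
                x$implied_mean, x$implied_sd))
  }
  invisible(x)
}

# stationarity via companion-matrix eigenvalues strictly inside the unit
# circle (the printed sufficient condition sum |rho_j| < 1 is too strong)
is_stationary_ar <- function(coefficients) {
  p <- length(coefficients)
  if (p == 0) return(TRUE)
  comp <- matrix(0, p, p)
  comp[1, ] <- coefficients
  if (p > 1) comp[cbind(2:p, 1:(p - 1))] <- 1
  all(Mod(eigen(comp, only.values = TRUE)$values) < 1)
}

#' Fit an AR(p) to an annual CO2 growth series
#'
#' Conditional maximum likelihood (least squares on the lagged design).
#' Diagnostics follow the usual time-series conventions: AIC/SBIC on the
#' `log(sigma2) + penalty/n` scale, Durbin-Watson on the residuals,
#' Jarque-Bera residual-normality p-value, and adjusted R-squared.
#'
#' @param series a [carbon_series()].
#' @param order AR order `P >= 1`.
#' @return an [ar_fit()] object with populated `diagnostics` (`aic`, `sbic`,
#'   `dw`, `jb_pvalue`, `adj_r2`) and `nobs`.
#' @export
fit_ar <- function(series, order) {
  stopifnot(inherits(series, "carbon_series"), order >= 1)
  y <- series$growth
  n_all <- length(y)
  if (n_all <= order + 10) {
    stop_invalid("series too short to fit AR(", order,
                 "): need more than order + 10 observations")
  }
  emb <- stats::embed(y, order + 1)           # col 1 = y_t, cols 2.. = lags
  yy <- emb[, 1]
  X <- cbind(1, emb[, -1, drop = FALSE])
  qrX <- qr(X)
  beta <- qr.coef(qrX, yy)
  res <- yy - X %*% beta
  n <- length(yy)
  k <- order + 1
  rss <- sum(res^2)
  sigma_xi <- sqrt(rss / (n - k))
  tss <- sum((yy - mean(yy))^2)
  adj_r2 <- 1 - (rss / (n - k)) / (tss / (n - 1))
  sk <- sample_skewness(as.numeric(res))
  ku <- sample_kurtosis(as.numeric(res)) - 3
  jb <- n / 6 * (sk^2 + ku^2 / 4)
  diag <- list(
    aic = log(rss / n) + 2 * k / n,
    sbic = log(rss / n) + k * log(n) / n,
    dw = sum(diff(as.numeric(res))^2) / rss,
    jb_pvalue = pchisq(jb, df = 2, lower.tail = FALSE),
    adj_r2 = adj_r2)
  fit <- ar_fit(intercept = beta[1], coefficients = beta[-1],
                innovation_sd = sigma_xi, diagnostics = diag, nobs = n)
  if (!fit$stationary) {
    warning("fitted AR coefficients are nonstationary", call. = FALSE)
  }
  fit
}

#' Select AR order by information criterion
#'
#' @param series a [carbon_series()].
#' @param orders candidate orders.
#' @param criterion `"aic"` or `"sbic"`.
#' @return the order minimising the criterion.
#' @export
select_ar_order <- function(series, orders = 1:3, criterion = c("aic", "sbic")) {
  criterion <- match.arg(criterion)
  vals <- vapply(orders, function(p) fit_ar(series, p)$diagnostics[[criterion]],
                 numeric(1))
  orders[which.min(vals)]
}

#' Stationary mean and sd of an AR(p) (Yule-Walker closed form)
#'
#' The mean is \eqn{\rho_0 / (1 - \sum_j \rho_j)}. The variance is obtained by
#' solving the Yule-Walker linear system for the autocorrelations
#' \eqn{r_1..r_P} (with \eqn{r_0 = 1}) and then
#' \eqn{\sigma_c^2 = \sigma_\xi^2 / (1 - \sum_j \rho_j r_j)}.
#'
#' @param fit an [ar_fit()].
#' @return named numeric vector `c(mean, sd)` (percent p.a.).
#' @export
stationary_moments <- function(fit) {
  rho <- fit$coefficients
  if (!is_stationary_ar(rho)) {
    stop_invalid("AR process is nonstationary; stationary moments undefined")
  }
  mu <- fit$intercept / (1 - sum(rho))
  r <- yule_walker_autocorr(rho)
  s2 <- fit$innovation_sd^2 / (1 - sum(rho * r))
  c(mean = mu, sd = sqrt(s2))
}

#' Yule-Walker autocorrelations of an AR(p)
#'
#' Solves the P-dimensional linear system
#' \eqn{r_k = \sum_j \rho_j r_{|k-j|}} for `k = 1..P` with `r_0 = 1`.
#'
#' @param rho AR coefficients.
#' @return autocorrelations `r_1..r_P` (length 0 when `P = 0`).
#' @export
yule_walker_autocorr <- function(rho) {
  p <- length(rho)
  if (p == 0) return(numeric(0))
  A <- diag(p)
  b <- rho
  for (k in seq_len(p)) {
    for (j in seq_len(p)) {
      lag <- abs(k - j)
      if (lag == 0) next
      A[k, lag] <- A[k, lag] - rho[j]
    }
  }
  as.numeric(solve(A, b))
}

#' Autocorrelation function of an AR(p) out to a given lag
#'
#' Extends the Yule-Walker solution recursively:
#' \eqn{r_k = \sum_j \rho_j r_{k-j}} for `k > P`. Used for closed-form
#' variances of lag-weighted sums of the carbon process.
#'
#' @param rho AR coefficients.
#' @param max_lag largest lag wanted.
#' @return numeric vector `r_0..r_max_lag` (with `r_0 = 1`).
#' @export
ar_acf <- function(rho, max_lag) {
  p <- length(rho)
  r <- c(1, if (p > 0) yule_walker_autocorr(rho))
  if (max_lag <= p) return(r[seq_len(max_lag + 1)])
  for (k in (p + 1):max_lag) {
    r <- c(r, sum(rho * r[k + 1 - seq_len(p)]))
  }
  r
}

#' Calibrate the AR intercept to a target stationary mean
#'
#' \eqn{\rho_0 = (1 - \sum_j \rho_j)\,\mu_c^{target}}.
#'
#' @param fit an [ar_fit()] (only the coefficients are used).
#' @param target_mean desired stationary mean, percent p.a.
#' @return the calibrated intercept \eqn{\rho_0}.
#' @export
calibrate_intercept_ar <- function(fit, target_mean) {
  check_finite_scalar(target_mean, "target_mean")
  if (sum(fit$coefficients) >= 1) {
    stop_invalid("sum of AR coefficients >= 1: nonstationary")
  }
  (1 - sum(fit$coefficients)) * target_mean
}

#' Retarget an AR model's stationary mean and sd
#'
#' Keeps the autoregressive coefficients, rescales the intercept via
#' [calibrate_intercept_ar()] and (optionally) the innovation sd so that the
#' stationary sd hits a target. Used by the RCP scenario evaluator, which
#' varies only the two stationary moments.
#'
#' @param fit an [ar_fit()].
#' @param target_mean desired stationary mean (percent p.a.), or `NULL` to
#'   keep the current one.
#' @param target_sd desired stationary sd (percent p.a., `>= 0`), or `NULL`.
#' @return a new [ar_fit()].
#' @export
retarget_ar <- function(fit, target_mean = NULL, target_sd = NULL) {
  mu <- if (is.null(target_mean)) fit$implied_mean else target_mean
  sxi <- fit$innovation_sd
  if (!is.null(target_sd)) {
    stopifnot(target_sd >= 0)
    sxi <- if (fit$implied_sd > 0) {
      fit$innovation_sd * target_sd / fit$implied_sd
    } else if (target_sd == 0) 0 else {
      stop_invalid("cannot rescale a degenerate (sd 0) process to positive sd")
    }
  }
  ar_fit(intercept = calibrate_intercept_ar(fit, mu),
         coefficients = fit$coefficients,
         innovation_sd = sxi,
         diagnostics = fit$diagnostics, nobs = fit$nobs)
}

#' Shock specification for carbon simulation
#'
#' Innovations are either Gaussian with sd \eqn{\sigma_\xi} or logistic with
#' location 0 and scale \eqn{s = \sigma_\xi} (so the logistic innovations
#' have sd \eqn{\sigma_\xi \pi / \sqrt 3}, roughly 1.8 times the Gaussian,
#' which fattens the simulated growth distribution).
#'
#' @param family `"gaussian"` or `"logistic"`.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return an object of class `"shock_spec"`.
#' @export
shock_spec <- function(family = c("gaussian", "logistic"), seed = NULL) {
  family <- match.arg(family)
  structure(list(family = family, seed = seed), class = "shock_spec")
}

# innovations matrix n x R on the given scale basis
draw_shocks <- function(spec, n, R, scale) {
  if (scale == 0) return(matrix(0, n, R))
  switch(spec$family,
         gaussian = matrix(rnorm(n * R, sd = scale), n, R),
         logistic = matrix(rlogis(n * R, location = 0, scale = scale), n, R))
}

# Internal engine: simulate R paths of length T (after burn-in) from a
# stationary AR(p); returns a T x R matrix. Initial states at the stationary
# mean; burn-in discards the transient.
simulate_carbon_paths <- function(fit, shocks, T, burn_in = 500, R = 1) {
  stopifnot(inherits(fit, "ar_fit"), T >= 1, R >= 1, burn_in >= 0)
  if (!fit$stationary) stop_invalid("refusing to simulate a nonstationary AR")
  p <- fit$order
  rho <- fit$coefficients
  if (!is.null(shocks$seed)) set.seed(shocks$seed)
  n <- T + burn_in
  eps <- draw_shocks(shocks, n, R, fit$innovation_sd)
  out <- matrix(fit$implied_mean, n + p, R)
  for (t in seq_len(n)) {
    i <- t + p
    lagpart <- if (p > 0) {
      drop(rho %*% out[i - seq_len(p), , drop = FALSE])
    } else 0
    out[i, ] <- fit$intercept + lagpart + eps[t, ]
  }
  out[(p + burn_in + 1):(p + n), , drop = FALSE]
}

#' Simulate one annual CO2 growth path
#'
#' Seeded, reproducible simulation of the stationary AR process; the
#' transient is removed with a burn-in and paths start at the stationary
#' mean.
#'
#' @param fit a stationary [ar_fit()].
#' @param shocks a [shock_spec()].
#' @param T number of years retained.
#' @param burn_in warm-up years discarded (default 500).
#' @param start_year calendar year of the first retained observation.
#' @return a [carbon_series()] of length `T`.
#' @export
simulate_carbon <- function(fit, shocks = shock_spec(), T, burn_in = 500,
                            start_year = 1960) {
  path <- simulate_carbon_paths(fit, shocks, T = T, burn_in = burn_in, R = 1)
  carbon_series(years = seq(start_year, length.out = T), growth = path[, 1])
}

#' Bootstrap confidence intervals for series moments
#'
#' iid resampling with replacement (matching an annual-frequency,
#' approximately exchangeable growth series); 95 percent percentile
#' intervals for the mean, sd, skewness and kurtosis.
#'
#' @param series a [carbon_series()] (length >= 10).
#' @param reps bootstrap replications (>= 100).
#' @param seed integer seed.
#' @return data frame with columns `statistic`, `estimate`, `lower`, `upper`.
#' @export
bootstrap_moments <- function(series, reps = 1000, seed = 1) {
  stopifnot(inherits(series, "carbon_series"))
  x <- series$growth
  if (length(x) < 10) stop_invalid("series too short to bootstrap (need >= 10)")
  if (reps < 100) stop_invalid("`reps` must be >= 100")
  set.seed(seed)
  stat_fun <- function(v) c(mean = mean(v), sd = sd(v),
                            skewness = sample_skewness(v),
                            kurtosis = sample_kurtosis(v))
  draws <- replicate(reps, stat_fun(sample(x, replace = TRUE)))
  est <- stat_fun(x)
  data.frame(
    statistic = names(est),
    estimate = as.numeric(est),
    lower = apply(draws, 1, quantile, 0.025, names = FALSE),
    upper = apply(draws, 1, quantile, 0.975, names = FALSE),
    row.names = NULL)
}
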