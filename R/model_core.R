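# Core logistic-transfer mathematics: the incidence function, certainty
# equivalent, intercept calibration, uncertainty wedge, cumulative response
# coefficients and disaster-count projections.

#' Logistic transfer parameters
#'
#' Container for the coefficients of the logistic incidence model
#' \deqn{p_{t+1} = \Lambda(\bar h + \sum_{j=0}^P h_j c_{t-j}
#'   + \sum_k \gamma_k X_{kt} + \delta p_t + \delta^c_i + \delta^g_t)}
#' where \eqn{\Lambda} is the logistic cdf, \eqn{c_{t-j}} is annual CO2
#' concentration growth in percent p.a. at lag \eqn{j}, the \eqn{X_{kt}} are
#' (log-transformed) controls, \eqn{\delta} is the persistence of incidence
#' and \eqn{\delta^c_i, \delta^g_t} are country and year fixed effects on
#' the log-odds scale.
#'
#' @param lag_coeffs numeric vector `h_0..h_P` of elasticities to CO2 growth
#'   (one per lag, lag 0 first). The lag order is `length(lag_coeffs) - 1`.
#' @param intercept scaling constant \eqn{\bar h} (log-odds); `NA` until
#'   calibrated via [calibrate_intercept()].
#' @param control_coeffs named or unnamed numeric vector of control
#'   elasticities \eqn{\gamma_k}.
#' @param persistence coefficient \eqn{\delta} on the lagged dependent term.
#' @param country_effects,time_effects optional named numeric vectors of
#'   fixed-effect offsets (log-odds); missing keys default to 0.
#' @return an object of class `"logit_params"`.
#' @export
logit_params <- function(lag_coeffs, intercept = NA_real_,
                         control_coeffs = numeric(0), persistence = 0,
                         country_effects = NULL, time_effects = NULL) {
  stopifnot(is.numeric(lag_coeffs), length(lag_coeffs) >= 1,
            all(is.finite(lag_coeffs)))
  if (!is.na(intercept)) check_finite_scalar(intercept, "intercept")
  check_finite_scalar(persistence, "persistence")
  structure(
    list(intercept = intercept,
         lag_coeffs = as.numeric(lag_coeffs),
         control_coeffs = control_coeffs,
         persistence = persistence,
         country_effects = country_effects,
         time_effects = time_effects,
         lag_order = length(lag_coeffs) - 1L),
    class = "logit_params")
}

#' @export
print.logit_params <- function(x, ...) {
  cat("Logistic transfer parameters (lag order P =", x$lag_order, ")\n")
  cat("  intercept h_bar :",
      if (is.na(x$intercept)) "uncalibrated" else format(x$intercept), "\n")
  cat("  lag coefficients:", paste(format(x$lag_coeffs), collapse = ", "),
      " (sum ", format(sum(x$lag_coeffs)), ")\n", sep = "")
  if (length(x$control_coeffs))
    cat("  controls gamma  :", paste(format(x$control_coeffs), collapse = ", "), "\n")
  cat("  persistence delta:", format(x$persistence), "\n")
  invisible(x)
}

#' Evaluation point for the transfer function
#'
#' The mean operating point at which the certainty-equivalent incidence is
#' evaluated: mean CO2 growth, per-control means of the transform entering
#' the model (e.g. mean log urban share), the lagged incidence, and optional
#' fixed-effect means (default 0).
#'
#' @param mu_c mean annual CO2 concentration growth, percent p.a.
#' @param covariate_means numeric vector, one entry per control coefficient.
#' @param p_bar lagged incidence probability in `[0, 1]`.
#' @param fe_mean mean fixed-effect offset (log-odds), default 0.
#' @return an object of class `"transfer_point"`.
#' @export
transfer_point <- function(mu_c, covariate_means = numeric(0), p_bar = 0,
                           fe_mean = 0) {
  check_finite_scalar(mu_c, "mu_c")
  check_finite_scalar(p_bar, "p_bar")
  if (p_bar < 0 || p_bar > 1) stop_invalid("`p_bar` must lie in [0, 1]")
  structure(list(mu_c = mu_c, covariate_means = covariate_means,
                 p_bar = p_bar, fe_mean = fe_mean),
            class = "transfer_point")
}

#' Numerically stable logistic (sigmoid) transfer
#'
#' Maps a log-odds value to a probability, `exp(x)/(1 + exp(x))`, without
#' overflow for large `|x|`.
#'
#' @param x numeric vector of log-odds; must be finite.
#' @return probabilities in (0, 1).
#' @export
logistic_transfer <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_invalid("`x` must be finite numeric")
  }
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Residual of the logistic / hyperbolic-tangent identity
#'
#' The centred logistic equals a scaled tanh:
#' \eqn{\Lambda(x) - 1/2 = \tanh(x/2)/2}. This returns the numerical residual
#' of that identity, which should vanish to machine precision; it is exposed
#' as a self-check of the transfer implementation.
#'
#' @param x numeric vector of log-odds; finite.
#' @return `logistic_transfer(x) - 1/2 - tanh(x/2)/2`.
#' @export
tanh_identity_residual <- function(x) {
  logistic_transfer(x) - 0.5 - 0.5 * tanh(x / 2)
}

# linear predictor at an evaluation point (log-odds scale)
linear_predictor <- function(params, point) {
  gam <- if (length(params$control_coeffs)) {
    if (length(point$covariate_means) != length(params$control_coeffs)) {
      stop_invalid("covariate_means length must match control_coeffs")
    }
    sum(params$control_coeffs * point$covariate_means)
  } else 0
  params$intercept + sum(params$lag_coeffs) * point$mu_c + gam +
    params$persistence * point$p_bar + point$fe_mean
}

#' Certainty-equivalent disaster incidence
#'
#' Evaluates the logistic transfer at the mean of its inputs: all lags of CO2
#' growth at `mu_c` (percent p.a.), controls at their means, lagged incidence
#' at `p_bar`, fixed effects at their supplied means (default 0). This is the
#' "no uncertainty" incidence \eqn{\bar\mu_p}.
#'
#' @param params a [logit_params()] with a non-`NA` intercept.
#' @param point a [transfer_point()].
#' @param mu_c_band plausibility band for `mu_c` in percent p.a.; values
#'   outside trigger a unit-mismatch warning (the model carries CO2 growth
#'   in percent, not fractions).
#' @return probability in (0, 1).
#' @export
certainty_equivalent <- function(params, point, mu_c_band = c(-5, 10)) {
  if (is.na(params$intercept)) {
    stop_invalid("params intercept is NA; calibrate or set it first")
  }
  if (point$mu_c < mu_c_band[1] || point$mu_c > mu_c_band[2]) {
    warning("mu_c = ", point$mu_c, " lies outside the plausibility band [",
            mu_c_band[1], ", ", mu_c_band[2],
            "] percent p.a.; check units (percent vs fraction)",
            call. = FALSE)
  }
  logistic_transfer(linear_predictor(params, point))
}

#' Calibrate the transfer intercept to a target incidence
#'
#' Solves for the scaling constant \eqn{\bar h^*} such that the
#' certainty-equivalent incidence at `point` equals `target` exactly:
#' \deqn{\bar h^* = \mathrm{logit}(target) - (\sum_j h_j)\mu_c
#'   - \sum_k \gamma_k \mu_k - \delta \bar p - \mathrm{fe}.}
#'
#' @inheritParams certainty_equivalent
#' @param target desired incidence, strictly inside (0, 1).
#' @return the calibrated intercept (log-odds scalar).
#' @seealso [calibrate_params()] which returns an updated parameter object.
#' @export
calibrate_intercept <- function(params, point, target) {
  check_finite_scalar(target, "target")
  if (target <= 0 || target >= 1) {
    stop_invalid("`target` must be strictly inside (0, 1)")
  }
  p0 <- params
  p0$intercept <- 0
  logit(target) - linear_predictor(p0, point)
}

#' Calibrated copy of a parameter set
#'
#' Convenience wrapper around [calibrate_intercept()] returning the updated
#' [logit_params()] object, stamped with the calibration point and target so
#' downstream simulation can refuse uncalibrated inputs.
#'
#' @inheritParams calibrate_intercept
#' @return a `logit_params` object with attribute `"calibration"`.
#' @export
calibrate_params <- function(params, point, target) {
  params$intercept <- calibrate_intercept(params, point, target)
  attr(params, "calibration") <- list(point = point, target = target)
  params
}

#' Uncertainty wedge between expected and certainty-equivalent incidence
#'
#' \eqn{UW_p = E[p] - \bar\mu_p}. Positive whenever the expectation is taken
#' over a spread confined to the convex region of the logistic (Jensen's
#' inequality); no clamping is applied, so a spread straddling the inflection
#' can yield a negative wedge.
#'
#' @param expected_p expected stochastic incidence, in `[0, 1]`.
#' @param mu_p_bar certainty-equivalent incidence, in `[0, 1]`.
#' @return the wedge (same units as the inputs).
#' @export
uncertainty_wedge <- function(expected_p, mu_p_bar) {
  stopifnot(all(expected_p >= 0 & expected_p <= 1),
            all(mu_p_bar >= 0 & mu_p_bar <= 1))
  expected_p - mu_p_bar
}

#' Cumulative response of certainty-equivalent incidence to CO2 growth
#'
#' The P-year cumulative semi-elasticity
#' \eqn{d\ln\bar\mu_p / d\mu_c \simeq S\, e^{-\mu_c S}/(1 + e^{-\mu_c S})}
#' with \eqn{S = \sum_j h_j}. Note the unit convention: here `mu_c` enters
#' as a *fraction* (e.g. 0.01624 for 1.624 percent p.a.), unlike the percent
#' convention used elsewhere in the transfer model.
#'
#' @param lag_sum sum of the lag elasticities \eqn{\sum_j h_j}.
#' @param mu_c_fraction mean CO2 growth as a fraction.
#' @return dimensionless response coefficient; algebraically equals
#'   `lag_sum * (1 - logistic_transfer(mu_c_fraction * lag_sum))`.
#' @export
cumulative_response <- function(lag_sum, mu_c_fraction) {
  check_finite_scalar(lag_sum, "lag_sum")
  check_finite_scalar(mu_c_fraction, "mu_c_fraction")
  lag_sum * logistic_transfer(-mu_c_fraction * lag_sum)
}

#' Project annual disaster-count growth from a response coefficient
#'
#' Multiplies the cumulative response by a percent rise in CO2 stock to get
#' the implied percent-per-year rise in the disaster count.
#'
#' @param response cumulative response coefficient, `>= 0`.
#' @param co2_rise_pct percent rise in CO2 concentration.
#' @return percent p.a. growth of the disaster count.
#' @export
project_disaster_growth <- function(response, co2_rise_pct) {
  stopifnot(response >= 0)
  response * co2_rise_pct
}

#' Doubling time of the disaster count
#'
#' Smallest integer number of years `n` with `(1 + g)^n >= 2`, i.e.
#' `ceiling(log(2) / log(1 + g))`.
#'
#' @param annual_growth growth rate as a fraction per year, strictly positive.
#' @return integer years.
#' @export
doubling_time <- function(annual_growth) {
  check_finite_scalar(annual_growth, "annual_growth")
  if (annual_growth <= 0) {
    stop_invalid("doubling time undefined for non-positive growth")
  }
  as.integer(ceiling(log(2) / log1p(annual_growth)))
}

#' Disaster-count projection report
#'
#' Bundles the response coefficient, the implied annual growth of the
#' disaster count, its doubling time, and the base and doubled counts per
#' country-year.
#'
#' @param lag_sum sum of lag elasticities.
#' @param mu_c_fraction mean CO2 growth as a fraction (see
#'   [cumulative_response()]).
#' @param co2_rise_pct percent rise in CO2 stock over the projection window.
#' @param base_count average disasters per country-year at the base.
#' @return an object of class `"response_report"`: a list with fields
#'   `response`, `annual_growth_pct`, `doubling_years`, `base_count`,
#'   `doubled_count`.
#' @export
response_report <- function(lag_sum, mu_c_fraction, co2_rise_pct,
                            base_count = 1.71) {
  response <- cumulative_response(lag_sum, mu_c_fraction)
  growth <- project_disaster_growth(response, co2_rise_pct)
  structure(
    list(response = response,
         annual_growth_pct = growth,
         doubling_years = doubling_time(growth / 100),
         base_count = base_count,
         doubled_count = 2 * base_count),
    class = "response_report")
}

#' @export
print.response_report <- function(x, ...) {
  cat(sprintf("Response d ln mu_p / d mu_c : %.2f\n", x$response))
  cat(sprintf("Disaster-count growth       : %.2f %% p.a.\n", x$annual_growth_pct))
  cat(sprintf("Doubling time               : %d years (%.2f -> %.2f events/country-year)\n",
              x$doubling_years, x$base_count, x$doubled_count))
  invisible(x)
}
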