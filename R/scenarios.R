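# IPCC RCP scenario evaluation: certainty-equivalent and simulated disaster
# risk per pathway, baseline vs stabilized CO2 growth variability, and
# discrete "decarbonisation dividend" gradients.

# canonical 2023-2100 mean CO2 growth per named pathway (percent p.a.)
.rcp_mu_c <- c("RCP2.6" = 0.19, "RCP3.4" = 0.34, "RCP4.5" = 0.56,
               "RCP6" = 0.91, "RCP8.5" = 1.54)

#' Baseline and stabilized CO2 growth variability
#'
#' The historical (1960-2022) stationary sd of annual CO2 growth is 0.68
#' percent p.a.; the stabilized-concentration scenario uses
#' \eqn{\sigma_c^{min} = 0.30} percent p.a.
#'
#' @return named numeric vector `c(baseline, stabilized)`.
#' @export
sigma_c_regimes <- function() c(baseline = 0.68, stabilized = 0.30)

#' RCP scenario specification
#'
#' @param name one of `"RCP2.6"`, `"RCP3.4"`, `"RCP4.5"`, `"RCP6"`,
#'   `"RCP8.5"` or `"custom"`. Named pathways carry canonical 2023-2100 mean
#'   CO2 growth rates (0.19, 0.34, 0.56, 0.91, 1.54 percent p.a.); custom
#'   scenarios must supply `mu_c` (see [mean_growth_from_endpoint()] for
#'   deriving it from a 2100 concentration level).
#' @param mu_c mean CO2 growth, percent p.a. (overrides the canonical value).
#' @param sigma_c stationary sd of CO2 growth, percent p.a. (>= 0).
#' @return an object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(name = "custom", mu_c = NULL,
                          sigma_c = sigma_c_regimes()[["baseline"]]) {
  if (is.null(mu_c)) {
    if (!name %in% names(.rcp_mu_c)) {
      stop_invalid("`mu_c` required for scenario '", name, "'")
    }
    mu_c <- .rcp_mu_c[[name]]
  }
  check_finite_scalar(mu_c, "mu_c")
  stopifnot(sigma_c >= 0)
  structure(list(name = name, mu_c = mu_c, sigma_c = sigma_c),
            class = "scenario_spec")
}

#' The five named RCP scenario specifications
#'
#' @param sigma_c stationary CO2 growth sd applied to every pathway.
#' @return named list of [scenario_spec()] objects.
#' @export
rcp_scenarios <- function(sigma_c = sigma_c_regimes()[["baseline"]]) {
  setNames(lapply(names(.rcp_mu_c), scenario_spec, sigma_c = sigma_c),
           names(.rcp_mu_c))
}

#' Mean annual growth implied by a 2100 concentration endpoint
#'
#' Continuous-compounding convention:
#' `100 * log(C_end / C_start) / years` percent p.a.
#'
#' @param c_start,c_end concentration levels in ppm (positive).
#' @param years horizon length in years (>= 1).
#' @return mean growth, percent p.a.
#' @export
mean_growth_from_endpoint <- function(c_start, c_end, years) {
  check_finite_scalar(c_start, "c_start")
  check_finite_scalar(c_end, "c_end")
  if (c_start <= 0 || c_end <= 0) stop_invalid("levels must be positive ppm")
  if (years < 1) stop_invalid("`years` must be >= 1")
  100 * log(c_end / c_start) / years
}

#' Certainty-equivalent incidence under a scenario
#'
#' Re-evaluates the calibrated transfer at the scenario's mean CO2 growth,
#' holding every non-carbon term (controls, persistence, fixed effects)
#' fixed at its calibration-point value.
#'
#' @param spec a [scenario_spec()].
#' @param params a calibrated [logit_params()] (see [calibrate_params()]).
#' @return certainty-equivalent incidence in percent p.a. (unrounded; report
#'   tables round half-away-from-zero to 1 d.p.).
#' @export
scenario_certainty_equivalent <- function(spec, params) {
  calib <- attr(params, "calibration")
  if (is.null(calib)) {
    stop_invalid("parameters must be calibrated (calibrate_params()) before ",
                 "scenario evaluation")
  }
  point <- calib$point
  point$mu_c <- spec$mu_c
  100 * certainty_equivalent(params, point)
}

#' Simulate disaster risk under a scenario
#'
#' Retargets the AR carbon template to the scenario's stationary mean and to
#' each requested sd regime (intercept via [calibrate_intercept_ar()];
#' innovation sd rescaled so the stationary sd matches, coefficients
#' unchanged), then runs [simulate_incidence()] per regime. `sigma_c = 0` is
#' handled as a degenerate deterministic run.
#'
#' @param spec a [scenario_spec()].
#' @param params a calibrated [logit_params()].
#' @param ar_template a stationary [ar_fit()] supplying the autoregressive
#'   coefficients.
#' @param sigmas named vector of stationary sd regimes to evaluate
#'   (default the scenario's own `sigma_c` plus the stabilized 0.30).
#' @param runs,horizon,burn_in,seed,shocks forwarded to
#'   [simulation_config()].
#' @return an object of class `"scenario_result"`: list with `spec`,
#'   `certainty_equivalent` (percent), and `summaries` (one
#'   [simulate_incidence()] summary per sd regime).
#' @export
scenario_simulation <- function(spec, params, ar_template,
                                sigmas = c(baseline = spec$sigma_c,
                                           stabilized = sigma_c_regimes()[["stabilized"]]),
                                runs = 2000, horizon = 2000, burn_in = 500,
                                seed = 1, shocks = shock_spec("gaussian")) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(ar_template, "ar_fit"))
  ce <- scenario_certainty_equivalent(spec, params)
  calib <- attr(params, "calibration")
  summaries <- lapply(seq_along(sigmas), function(i) {
    ar_s <- retarget_ar(ar_template, target_mean = spec$mu_c,
                        target_sd = sigmas[[i]])
    # scenario point: the calibration stamp must reflect the scenario mean so
    # the simulated certainty equivalent matches scenario_certainty_equivalent
    pars <- params
    pt <- calib$point
    pt$mu_c <- spec$mu_c
    attr(pars, "calibration") <- list(point = pt, target = ce / 100)
    # every non-carbon term (controls, persistence, fixed effects) is frozen
    # at its calibration value, mirroring the certainty-equivalent convention
    cfg <- simulation_config(pars, ar_s, runs = runs, horizon = horizon,
                             burn_in = burn_in, shocks = shocks,
                             dynamic = "fixed",
                             seed = derive_seed(seed, paste0(spec$name, "/",
                                                             names(sigmas)[i])))
    simulate_incidence(cfg)
  })
  names(summaries) <- names(sigmas)
  structure(list(spec = spec, certainty_equivalent = ce,
                 summaries = summaries),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario", x$spec$name, sprintf("(mu_c = %.2f %% p.a.)\n", x$spec$mu_c))
  cat(sprintf("  certainty equivalent: %.1f %% p.a.\n",
              round_half_up(x$certainty_equivalent, 1)))
  for (nm in names(x$summaries)) {
    s <- x$summaries[[nm]]
    cat(sprintf("  %-10s E[mu_p] = %.2f %% [%.1f, %.1f], wedge = %.2f %%\n",
                nm, 100 * s$expected_mean, 100 * s$ci["mean", 1],
                100 * s$ci["mean", 2], 100 * s$expected_wedge))
  }
  invisible(x)
}

#' Decarbonisation dividend gradients across scenarios
#'
#' Discrete analogues of the response coefficient: for each non-reference
#' scenario, `(value(s) - value(ref)) / (mu_c(s) - mu_c(ref))` for both the
#' certainty-equivalent and the simulated mean incidence (computed from
#' unrounded internal values).
#'
#' @param results named list of [scenario_simulation()] results.
#' @param reference name of the reference scenario (must be present).
#' @param regime which sd regime's simulated mean to use.
#' @return data frame with columns `scenario`, `mu_c`, `ce`, `sim_mean`,
#'   `grad_ce`, `grad_sim` (gradients `NA` for the reference row).
#' @export
decarbonisation_gradient <- function(results, reference = "RCP2.6",
                                     regime = "baseline") {
  stopifnot(reference %in% names(results))
  ref <- results[[reference]]
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    dmu <- r$spec$mu_c - ref$spec$mu_c
    sim <- 100 * r$summaries[[regime]]$expected_mean
    sim_ref <- 100 * ref$summaries[[regime]]$expected_mean
    data.frame(
      scenario = nm,
      mu_c = r$spec$mu_c,
      ce = r$certainty_equivalent,
      sim_mean = sim,
      grad_ce = if (nm == reference || dmu == 0) NA_real_ else
        (r$certainty_equivalent - ref$certainty_equivalent) / dmu,
      grad_sim = if (nm == reference || dmu == 0) NA_real_ else
        (sim - sim_ref) / dmu)
  })
  do.call(rbind, rows)
}

#' Full RCP sensitivity table
#'
#' Evaluates the five named pathways under baseline and stabilized CO2
#' growth variability, producing a long-format table of certainty
#' equivalents, simulated means, wedges, higher moments and gradients
#' (statistics in percent where applicable).
#'
#' @param params a calibrated [logit_params()].
#' @param ar_template a stationary [ar_fit()].
#' @param runs,horizon,burn_in,seed forwarded to [scenario_simulation()].
#' @return list with `results` (named list of scenario results) and `table`
#'   (data frame: scenario, mu_c, regime, ce, mean_lo, mean_hi, wedge_lo,
#'   wedge_hi, sd_lo, sd_hi, skew_lo, skew_hi, kurt_lo, kurt_hi).
#' @export
run_rcp_table <- function(params, ar_template, runs = 2000, horizon = 2000,
                          burn_in = 500, seed = 1) {
  specs <- rcp_scenarios()
  results <- lapply(specs, scenario_simulation, params = params,
                    ar_template = ar_template, runs = runs,
                    horizon = horizon, burn_in = burn_in, seed = seed)
  rows <- list()
  for (nm in names(results)) {
    r <- results[[nm]]
    for (reg in names(r$summaries)) {
      s <- r$summaries[[reg]]
      rows[[length(rows) + 1]] <- data.frame(
        scenario = nm, mu_c = r$spec$mu_c, regime = reg,
        ce = round_half_up(r$certainty_equivalent, 1),
        mean_lo = 100 * s$ci["mean", 1], mean_hi = 100 * s$ci["mean", 2],
        wedge_lo = 100 * s$wedge_ci[[1]], wedge_hi = 100 * s$wedge_ci[[2]],
        sd_lo = 100 * s$ci["sd", 1], sd_hi = 100 * s$ci["sd", 2],
        skew_lo = s$ci["skewness", 1], skew_hi = s$ci["skewness", 2],
        kurt_lo = s$ci["kurtosis", 1], kurt_hi = s$ci["kurtosis", 2])
    }
  }
  list(results = results, table = do.call(rbind, c(rows, make.row.names = FALSE)))
}
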