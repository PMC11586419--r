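# Synthetic fixtures with the statistical structure the analysis assumes:
# an AR(3)-driven annual CO2 growth record and a country-year disaster panel
# generated from the logistic model with country fixed effects. Everything
# is a pure function of (spec, seed), so the whole pipeline is testable
# offline.

#' Generate a synthetic annual CO2 growth history
#'
#' Simulates the stationary AR process (default: the historical AR(3)
#' calibration, stationary mean 1.624 percent p.a.) for a 63-year annual
#' record, optionally integrating a ppm level track from the growth rates.
#'
#' @param fit a stationary [ar_fit()] (default [reference_ar3()]).
#' @param years calendar years of the growth observations.
#' @param seed integer seed.
#' @param base_ppm concentration level (ppm) in the year before the first
#'   growth observation, used to integrate the level track; `NULL` to skip.
#' @param shocks a [shock_spec()] (its seed is superseded by `seed`).
#' @return a [carbon_series()] with growth and (optionally) levels.
#' @export
generate_carbon_history <- function(fit = reference_ar3(),
                                    years = 1960:2022, seed = 1,
                                    base_ppm = 316.9,
                                    shocks = shock_spec("gaussian")) {
  if (!fit$stationary) stop_invalid("refusing a nonstationary AR spec")
  shocks$seed <- derive_seed(seed, "carbon")
  Tn <- length(years)
  path <- simulate_carbon_paths(fit, shocks, T = Tn, burn_in = 500, R = 1)[, 1]
  out <- carbon_series(years = years, growth = path)
  if (!is.null(base_ppm)) {
    out$levels <- base_ppm * exp(cumsum(path / 100))
    out$level_years <- years
  }
  out
}

#' Specification for the synthetic disaster-panel generator
#'
#' @param n_countries number of countries (>= 1).
#' @param years calendar years of the panel.
#' @param params true [logit_params()] (intercept may be `NA`: it is then
#'   calibrated internally so pooled incidence hits `target_incidence`).
#' @param country_sd sd `tau` of the Normal(0, tau) country effects on the
#'   log-odds scale.
#' @param target_incidence pooled annual incidence the generator calibrates
#'   its intercept to.
#' @param carbon a [carbon_series()] to use as the shared forcing, or `NULL`
#'   to generate one from `ar_spec`.
#' @param ar_spec an [ar_fit()] used when `carbon` is `NULL`.
#' @param seed integer master seed.
#' @return an object of class `"panel_generator_spec"`.
#' @export
panel_generator_spec <- function(n_countries = 200, years = 1960:2022,
                                 params = reference_logit_params("one_way_urban"),
                                 country_sd = 0.5,
                                 target_incidence = 0.062,
                                 carbon = NULL,
                                 ar_spec = reference_ar3(),
                                 seed = 1) {
  if (n_countries < 1) stop_invalid("`n_countries` must be >= 1")
  stopifnot(inherits(params, "logit_params"), country_sd >= 0,
            target_incidence > 0, target_incidence < 1)
  structure(list(n_countries = n_countries, years = years, params = params,
                 country_sd = country_sd, target_incidence = target_incidence,
                 carbon = carbon, ar_spec = ar_spec, seed = seed),
            class = "panel_generator_spec")
}

# deterministic per-country logistic urban-share growth curve, bounded in
# (0, 1); curve parameters are drawn once from the seeded RNG
urban_share_curves <- function(n_countries, years) {
  ceiling_i <- runif(n_countries, 0.55, 0.95)
  rate_i <- runif(n_countries, 0.02, 0.08)
  midpoint_i <- runif(n_countries, 1975, 2005)
  t(vapply(seq_len(n_countries), function(i) {
    ceiling_i[i] / (1 + exp(-rate_i[i] * (years - midpoint_i[i])))
  }, numeric(length(years))))
}

#' Generate a synthetic country-year disaster panel
#'
#' Binary events are drawn from the logistic model with Normal country
#' effects, a deterministic per-country logistic urban-share growth curve,
#' lagged-state dynamics and a shared carbon forcing. The intercept is
#' calibrated numerically (root finding on the panel-averaged model
#' probability, with the lagged-state term handled by the exact two-state
#' probability recursion) so pooled incidence matches the target.
#'
#' @param spec a [panel_generator_spec()].
#' @return a [disaster_panel()] with attributes `"true_params"` (the
#'   calibrated [logit_params()]), `"carbon"` (the forcing series) and
#'   `"implied_incidence"` (panel-average model probability).
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_generator_spec"))
  params <- spec$params
  years <- spec$years
  n <- spec$n_countries
  P <- params$lag_order
  carbon <- spec$carbon
  if (is.null(carbon)) {
    # events in year t are driven by growth lags c_{t-1-j}, j = 0..P, so the
    # forcing must reach back P + 1 years before the first panel year
    carbon <- generate_carbon_history(spec$ar_spec,
                                      years = (min(years) - P - 1):max(years),
                                      seed = derive_seed(spec$seed, "panel-carbon"),
                                      base_ppm = NULL)
  }
  cmap <- setNames(carbon$growth, carbon$years)
  need <- (min(years) - P - 1):(max(years) - 1)
  if (!all(need %in% carbon$years)) {
    stop_invalid("carbon forcing does not cover panel years minus ", P + 1,
                 " lags")
  }

  set.seed(derive_seed(spec$seed, "panel"))
  a_i <- rnorm(n, 0, spec$country_sd)
  urban <- urban_share_curves(n, years)            # n x T
  Tn <- length(years)
  h <- params$lag_coeffs
  # carbon lag combination per panel year (events in year t are driven by
  # information dated t - 1: growth lags c_{t-1-j}, covariate X_{i,t-1})
  xc <- vapply(years, function(y) {
    sum(h * as.numeric(cmap[as.character(y - 1 - (0:P))]))
  }, numeric(1))
  gam <- if (length(params$control_coeffs)) params$control_coeffs[[1]] else 0
  delta <- params$persistence

  # base log-odds (without intercept and lag-state term), n x T;
  # covariate lagged one year, first column reuses the first curve value
  lag_urban <- cbind(urban[, 1, drop = FALSE], urban[, -Tn, drop = FALSE])
  base <- matrix(xc, n, Tn, byrow = TRUE) + gam * log(lag_urban) + a_i

  # exact pooled model probability via the two-state recursion
  # q_{t+1} = q_t * L(x + delta) + (1 - q_t) * L(x)
  pooled_prob <- function(h_bar) {
    q <- matrix(spec$target_incidence, n, 1)
    acc <- 0
    for (t in seq_len(Tn)) {
      x <- h_bar + base[, t]
      pt <- q * logistic_transfer(x + delta) + (1 - q) * logistic_transfer(x)
      acc <- acc + sum(pt)
      q <- pt
    }
    acc / (n * Tn)
  }
  h_bar <- if (is.na(params$intercept)) {
    f <- function(b) pooled_prob(b) - spec$target_incidence
    lo <- logit(spec$target_incidence) - 30
    hi <- logit(spec$target_incidence) + 30
    if (f(lo) > 0 || f(hi) < 0) {
      stop_invalid("target incidence unreachable with the supplied coefficients")
    }
    uniroot(f, c(lo, hi), tol = 1e-10)$root
  } else params$intercept
  implied <- pooled_prob(h_bar)
  if (implied <= 0 || implied >= 1) {
    stop_invalid("implied pooled incidence outside (0, 1)")
  }

  # draw binary events with lagged-state dynamics
  s <- matrix(0L, n, Tn)
  prev <- rbinom(n, 1, spec$target_incidence)
  for (t in seq_len(Tn)) {
    p_t <- logistic_transfer(h_bar + base[, t] + delta * prev)
    s[, t] <- rbinom(n, 1, p_t)
    prev <- s[, t]
  }

  countries <- sprintf("C%03d", seq_len(n))
  pan <- disaster_panel(
    country = rep(countries, each = Tn),
    year = rep(years, times = n),
    events = as.integer(t(s)),
    urban_share = as.numeric(t(urban)))
  true <- params
  true$intercept <- h_bar
  attr(pan, "true_params") <- true
  attr(pan, "carbon") <- carbon
  attr(pan, "implied_incidence") <- implied
  pan
}

#' Write seeded default fixtures to disk
#'
#' Writes a carbon series and a disaster panel in the package's delimited
#' text formats, plus a DCF manifest recording the seed and the true
#' generator parameters. Re-running with the same seed reproduces the data
#' files byte-identically.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer master seed.
#' @param spec optional [panel_generator_spec()]; default uses `seed`.
#' @return named character vector of the three file paths (carbon, panel,
#'   manifest), invisibly.
#' @export
write_fixtures <- function(out_dir, seed = 1, spec = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_invalid("cannot create output directory ", out_dir)
  }
  if (is.null(spec)) spec <- panel_generator_spec(seed = seed)
  pan <- generate_panel(spec)
  carbon <- attr(pan, "carbon")
  true <- attr(pan, "true_params")

  carbon_path <- file.path(out_dir, "carbon.csv")
  panel_path <- file.path(out_dir, "panel.csv")
  manifest_path <- file.path(out_dir, "manifest.dcf")
  write_carbon_csv(carbon, carbon_path, seed = spec$seed)
  write_panel_csv(pan, panel_path, seed = spec$seed)
  manifest <- data.frame(
    seed = spec$seed,
    n_countries = spec$n_countries,
    years = paste(range(spec$years), collapse = "-"),
    target_incidence = spec$target_incidence,
    country_sd = spec$country_sd,
    intercept = format(true$intercept, digits = 12),
    lag_coeffs = paste(format(true$lag_coeffs, digits = 12), collapse = " "),
    control_coeffs = paste(format(true$control_coeffs, digits = 12),
                           collapse = " "),
    persistence = format(true$persistence, digits = 12))
  write.dcf(manifest, manifest_path)
  invisible(c(carbon = carbon_path, panel = panel_path,
              manifest = manifest_path))
}

#' Read a fixture manifest back into generator parameters
#'
#' Parses the DCF manifest written by [write_fixtures()]; the true-parameter
#' block round-trips through this reader.
#'
#' @param path manifest file path.
#' @return list with `seed`, `target_incidence`, and `params`
#'   (a [logit_params()]).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_invalid("manifest not found: ", path)
  d <- as.data.frame(read.dcf(path), stringsAsFactors = FALSE)
  num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  ctrl <- if (nzchar(trimws(d$control_coeffs))) num(d$control_coeffs) else numeric(0)
  list(seed = as.integer(d$seed),
       target_incidence = as.numeric(d$target_incidence),
       params = logit_params(lag_coeffs = num(d$lag_coeffs),
                             intercept = as.numeric(d$intercept),
                             control_coeffs = ctrl,
                             persistence = as.numeric(d$persistence)))
}
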