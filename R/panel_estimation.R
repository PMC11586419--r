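# Dynamic panel logit with one-/two-way fixed effects on a country-year
# disaster panel, plus AUROC classification skill and McFadden pseudo-R2.

#' Country-year disaster panel
#'
#' Validates and wraps a country-year panel of disaster indicators. The
#' binary state `event` is 1 when at least one climate-related event was
#' recorded that year (multiple concurrent events collapse to 1 for the
#' dependent variable; counts are retained for reporting).
#'
#' @param country character or factor country identifiers.
#' @param year integer calendar years.
#' @param events integer event counts (>= 0).
#' @param urban_share urban population share, fraction in (0, 1].
#' @return a data frame of class `"disaster_panel"` with columns `country`,
#'   `year`, `events`, `event`, `urban_share`.
#' @export
disaster_panel <- function(country, year, events, urban_share) {
  stopifnot(length(country) == length(year),
            length(events) == length(year),
            length(urban_share) == length(year))
  if (any(events < 0)) stop_invalid("`events` must be non-negative counts")
  if (any(!is.na(urban_share) & (urban_share <= 0 | urban_share > 1))) {
    stop_invalid("`urban_share` must lie in (0, 1]")
  }
  key <- paste(country, year)
  if (anyDuplicated(key)) {
    stop_invalid("duplicate (country, year) pairs in panel: ",
                 paste(head(unique(key[duplicated(key)]), 3), collapse = ", "))
  }
  structure(
    data.frame(country = as.character(country), year = as.integer(year),
               events = as.integer(events),
               event = as.integer(events > 0),
               urban_share = urban_share,
               stringsAsFactors = FALSE),
    class = c("disaster_panel", "data.frame"))
}

#' Build the dynamic panel logit design
#'
#' Constructs estimation rows with outcome \eqn{s_{i,t+1}} regressed on the
#' global CO2 growth terms \eqn{c_t .. c_{t-P}} (percent p.a.), the log
#' urban share \eqn{\log X_{it}}, the lagged binary state \eqn{s_{it}}, and
#' fixed-effect factors per `fe`. The first `P + 1` panel years are lost to
#' lag construction. Countries (and under two-way FE, years) whose outcomes
#' are all zero or all one are flagged: their fixed-effect dummy is not
#' identified (perfect-separation risk).
#'
#' @param panel a [disaster_panel()].
#' @param carbon a [carbon_series()] covering the panel years minus `P` lags.
#' @param P lag order (>= 0).
#' @param fe fixed effects: `"none"`, `"one_way"` (country) or `"two_way"`
#'   (country + year).
#' @param use_urban include the log urban-share control.
#' @return an object of class `"panel_design"`: list with the model `data`
#'   (columns `y`, `c_lag0..c_lagP`, optionally `log_urban`, `lag_state`,
#'   `country`, `year`), `fe`, `P`, counters of dropped rows, and the flagged
#'   degenerate countries/years.
#' @export
build_design <- function(panel, carbon, P = 3,
                         fe = c("none", "one_way", "two_way"),
                         use_urban = TRUE) {
  fe <- match.arg(fe)
  stopifnot(inherits(panel, "disaster_panel"), inherits(carbon, "carbon_series"))
  if (P < 0) stop_invalid("`P` must be >= 0")
  yrs <- sort(unique(panel$year))
  outcome_years <- yrs[yrs >= min(yrs) + P + 1]
  need <- (min(outcome_years) - 1 - P):(max(outcome_years) - 1)
  if (!all(need %in% carbon$years)) {
    stop_invalid("carbon series does not cover required years ",
                 min(need), "-", max(need))
  }
  cmap <- setNames(carbon$growth, carbon$years)

  # outcome row (i, tau): regressors dated tau - 1
  pan <- panel[order(panel$country, panel$year), ]
  idx <- match(paste(pan$country, pan$year - 1), paste(pan$country, pan$year))
  dat <- data.frame(country = pan$country, year = pan$year, y = pan$event,
                    stringsAsFactors = FALSE)
  dat$lag_state <- pan$event[idx]
  dat$log_urban <- if (use_urban) log(pan$urban_share[idx]) else NULL
  for (j in 0:P) {
    dat[[paste0("c_lag", j)]] <- as.numeric(cmap[as.character(dat$year - 1 - j)])
  }
  dat <- dat[dat$year %in% outcome_years, , drop = FALSE]
  n_before <- nrow(dat)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  dropped <- n_before - nrow(dat)
  if (dropped > 0) {
    message("build_design: dropped ", dropped, " rows with missing covariates")
  }

  deg_country <- names(which(tapply(dat$y, dat$country,
                                    function(v) all(v == v[1]))))
  deg_year <- names(which(tapply(dat$y, dat$year,
                                 function(v) all(v == v[1]))))
  structure(
    list(data = dat, fe = fe, P = P, use_urban = use_urban,
         dropped_rows = dropped,
         degenerate_countries = deg_country,
         degenerate_years = deg_year),
    class = "panel_design")
}

#' Fit the dynamic panel logit by maximum likelihood
#'
#' Fixed effects enter as dummy coefficients (the incidental-parameter bias
#' of dummy-variable logit at short panels is accepted and documented; no
#' conditional-logit sufficiency reduction is applied). Countries - and
#' under two-way FE, years - with all-zero or all-one outcomes are excluded
#' before fitting (their dummies are unidentified), which is reflected in
#' `n_obs`.
#'
#' @param design a [build_design()] result.
#' @param cluster_robust compute country-clustered sandwich standard errors
#'   instead of the classical ML covariance.
#' @param drop_degenerate drop degenerate fixed-effect groups (default). With
#'   `FALSE`, their presence under FE raises a perfect-separation error
#'   naming the offending groups.
#' @return an object of class `"logit_fit"`: list with `params`
#'   (a [logit_params()] holding lag, control, persistence and fixed-effect
#'   estimates), `coefficients`, `covariance`, `se`, `loglik`, `null_loglik`,
#'   `pseudo_r2`, `auroc`, `n_obs`, `converged`, `fitted`, `outcomes`.
#' @export
fit_panel_logit <- function(design, cluster_robust = FALSE,
                            drop_degenerate = TRUE) {
  stopifnot(inherits(design, "panel_design"))
  dat <- design$data
  fe <- design$fe
  if (fe %in% c("one_way", "two_way") && length(design$degenerate_countries)) {
    if (!drop_degenerate) {
      stop_invalid("perfect separation: country fixed effect unidentified for ",
                   paste(design$degenerate_countries, collapse = ", "))
    }
    dat <- dat[!dat$country %in% design$degenerate_countries, , drop = FALSE]
  }
  if (fe == "two_way" && length(design$degenerate_years)) {
    if (!drop_degenerate) {
      stop_invalid("perfect separation: year fixed effect unidentified for ",
                   paste(design$degenerate_years, collapse = ", "))
    }
    dat <- dat[!dat$year %in% design$degenerate_years, , drop = FALSE]
  }
  if (nrow(dat) == 0 || length(unique(dat$y)) < 2) {
    stop_invalid("perfect separation: outcomes are single-class after ",
                 "dropping degenerate groups")
  }

  lag_terms <- paste0("c_lag", 0:design$P)
  rhs <- c(lag_terms,
           if (design$use_urban) "log_urban",
           "lag_state",
           switch(fe, none = NULL, one_way = "factor(country)",
                  two_way = c("factor(country)", "factor(year)")))
  form <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  fit <- suppressWarnings(glm(form, family = binomial(), data = dat))
  converged <- isTRUE(fit$converged) && !fit$boundary &&
    max(abs(coef(fit)[lag_terms])) < 50
  if (!converged) {
    warning("panel logit did not converge cleanly; estimates flagged",
            call. = FALSE)
  }

  cf <- coef(fit)
  # with two-way FE the global carbon lags lie in the span of the year
  # dummies; glm then aliases trailing collinear columns (NA coefficients).
  # The carbon terms come first in the formula so they stay identified up to
  # that normalisation; aliased dummies are dropped here.
  if (anyNA(cf)) {
    if (anyNA(cf[lag_terms])) {
      stop_invalid("carbon lag coefficients are not identified (aliased)")
    }
    cf <- cf[!is.na(cf)]
  }
  V <- if (cluster_robust) cluster_vcov(fit, dat$country) else vcov(fit)
  ce <- cf[grep("^factor\\(country\\)", names(cf))]
  names(ce) <- sub("^factor\\(country\\)", "", names(ce))
  te <- cf[grep("^factor\\(year\\)", names(cf))]
  names(te) <- sub("^factor\\(year\\)", "", names(te))
  params <- logit_params(
    lag_coeffs = unname(cf[lag_terms]),
    intercept = unname(cf["(Intercept)"]),
    control_coeffs = if (design$use_urban) c(log_urban = unname(cf["log_urban"])) else numeric(0),
    persistence = unname(cf["lag_state"]),
    country_effects = if (length(ce)) ce else NULL,
    time_effects = if (length(te)) te else NULL)

  ll <- as.numeric(logLik(fit))
  null_fit <- glm(y ~ 1, family = binomial(), data = dat)
  ll0 <- as.numeric(logLik(null_fit))
  scores <- fitted(fit)
  structure(
    list(params = params,
         coefficients = cf,
         covariance = V,
         se = sqrt(diag(V)),
         loglik = ll,
         null_loglik = ll0,
         pseudo_r2 = pseudo_r2(ll, ll0),
         auroc = auroc(scores, dat$y),
         n_obs = nrow(dat),
         converged = converged,
         fitted = scores,
         outcomes = dat$y,
         fe = fe,
         glm = fit),
    class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("Dynamic panel logit (", x$fe, " fixed effects)\n", sep = "")
  cat("  n_obs =", x$n_obs, " converged:", x$converged, "\n")
  cat(sprintf("  pseudo R2 = %.3f  AUROC = %.4f\n", x$pseudo_r2, x$auroc))
  cat("  lag coefficients:",
      paste(sprintf("%.3f", x$params$lag_coeffs), collapse = ", "), "\n")
  invisible(x)
}

# country-clustered sandwich covariance for a binomial glm
cluster_vcov <- function(fit, cluster) {
  X <- model.matrix(fit)
  res <- fit$y - fitted(fit)
  scores <- X * res
  G <- length(unique(cluster))
  meat <- crossprod(rowsum(scores, cluster))
  bread <- vcov(fit)
  adj <- G / (G - 1)
  adj * bread %*% meat %*% bread
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Fraction of (positive, negative) outcome pairs in which the positive
#' case's score is strictly higher, with ties counted one half. Computed in
#' `O(n log n)` via midranks.
#'
#' @param scores numeric model scores (e.g. fitted probabilities).
#' @param outcomes binary outcomes (0/1), at least one of each class.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, outcomes) {
  stopifnot(length(scores) == length(outcomes))
  outcomes <- as.integer(outcomes)
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  if (n1 == 0 || n0 == 0) {
    stop_invalid("AUROC undefined: need at least one positive and one negative")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' McFadden pseudo R-squared
#'
#' \eqn{1 - \ell / \ell_0} for a fitted log-likelihood \eqn{\ell} and the
#' intercept-only null \eqn{\ell_0}; lies in `[0, 1)` for a nested null.
#'
#' @param loglik fitted model log-likelihood.
#' @param null_loglik null (intercept-only) log-likelihood; must be nonzero.
#' @return scalar.
#' @export
pseudo_r2 <- function(loglik, null_loglik) {
  check_finite_scalar(loglik, "loglik")
  check_finite_scalar(null_loglik, "null_loglik")
  if (null_loglik == 0) stop_invalid("null log-likelihood is zero")
  1 - loglik / null_loglik
}
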