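# Shared fixtures, built in code.

# calibrated one-way urban reference parameters at the historical baseline
calibrated_baseline <- function(spec = "one_way_urban", target = 0.062,
                                mu_c = 1.624) {
  params <- reference_logit_params(spec)
  calibrate_params(params, baseline_point(params, mu_c = mu_c, p_bar = target),
                   target)
}

# small deterministic disaster panel: `pattern` is a list country -> event
# vector over `years`
toy_panel <- function(pattern, years, urban = 0.5) {
  countries <- names(pattern)
  disaster_panel(
    country = rep(countries, each = length(years)),
    year = rep(years, times = length(countries)),
    events = unlist(pattern, use.names = FALSE),
    urban_share = rep(rep_len(urban, length(years)), times = length(countries)))
}

# deterministic carbon series over `years` (values cycle if short)
toy_carbon <- function(years, values = c(1.2, 1.6, 1.9, 1.4, 1.7)) {
  carbon_series(years, growth = rep_len(values, length(years)))
}

# O(n^2) brute-force AUROC oracle: pair counting with ties = 1/2
auroc_bruteforce <- function(scores, outcomes) {
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Gaussian quadrature oracle for E[logistic(a + b * C)], C ~ N(mu, sd)
quad_expected_logistic <- function(a, b, mu, sd) {
  if (sd == 0) return(plogis(a + b * mu))
  stats::integrate(function(c) plogis(a + b * c) * dnorm(c, mu, sd),
                   mu - 10 * sd, mu + 10 * sd, rel.tol = 1e-10)$value
}
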