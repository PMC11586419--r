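---
title: "Modelling climate-disaster incidence from stochastic CO2 growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling climate-disaster incidence from stochastic CO2 growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbonwedge)
```

## The model

`carbonwedge` models the *incidence rate* — the annual conditional
probability that a country records at least one climate-related disaster
(flood, storm, drought, wildfire, heatwave, extreme cold) — as a logistic
function of present and lagged growth in global atmospheric CO2
concentration:

$$
p_{t+1} \;=\; \Lambda\Big(\bar h + \sum_{j=0}^{P} h_j\, c_{t-j}
  + \gamma \log X_{it} + \delta\, p_{it}
  + \delta^c_i + \delta^g_t\Big),
\qquad \Lambda(x) = \frac{e^x}{1+e^x},
$$

where $c_t = 100\,\Delta\log C_t$ is annual CO2 concentration growth in
percent p.a., $X_{it}$ is the urban population share (the socio-economic
control), $\delta$ the persistence of incidence, and $\delta^c_i$,
$\delta^g_t$ country and year fixed effects. The lag order is $P = 3$
throughout: three years of carbon growth history carry information about
next year's disaster likelihood.

Two derived quantities organise everything:

* the **certainty-equivalent incidence** $\bar\mu_p$ — the transfer
  evaluated at the *mean* of its inputs (mean CO2 growth $\mu_c$, mean
  controls, no shock); and
* the **uncertainty wedge** $UW_p = E[\tilde p] - \bar\mu_p$ — the gap
  between *expected* incidence under stochastic carbon growth and the
  certainty equivalent. Because $\Lambda$ is strictly convex left of its
  inflection point (and every calibrated operating point here sits deep in
  that region, $\bar\mu_p \approx 6\%$), Jensen's inequality makes the
  wedge positive, and it widens with both the mean and the variance of
  carbon growth. The package verifies the underlying identity
  $\Lambda(x) - \tfrac12 = \tfrac12\tanh(x/2)$ numerically
  (`tanh_identity_residual()`).

The practical reading: a policymaker using historical average incidence as
a "best guess" underestimates expected disaster frequency whenever carbon
growth is uncertain, and stabilising CO2 growth (smaller $\sigma_c$) is an
independent risk-mitigation channel on top of decarbonisation (smaller
$\mu_c$).

## Calibration conventions

The intercept $\bar h$ is never taken from a printed table; it is always
derived by `calibrate_intercept()` so that the certainty equivalent at the
historical operating point — $\mu_c = 1.624$ % p.a., pooled incidence
target 6.2 % — is exact:

```{r}
params <- reference_logit_params("one_way_urban")
point  <- baseline_point(params, p_bar = 0.062)
params <- calibrate_params(params, point, target = 0.062)
params$intercept
certainty_equivalent(params, point)
```

Two unit conventions coexist, both retained deliberately because each
reproduces a different published quantity:

* the transfer model carries CO2 growth in **percent p.a.** (1.624), which
  reproduces the scenario certainty-equivalent row (1.0 / 1.2 / 1.6 / 2.5 /
  5.6 % p.a. across RCP2.6–RCP8.5);
* the cumulative response coefficient
  $d\ln\bar\mu_p/d\mu_c \simeq S\,e^{-\mu_c S}/(1+e^{-\mu_c S})$,
  $S=\sum_j h_j$, is evaluated with $\mu_c$ as a **fraction** (0.01624),
  which reproduces the published response row (0.77 / 0.70 / 0.79 / 0.65 /
  1.11). `cumulative_response()` documents this explicitly.

The printed two-way/no-control response value 0.91 is *not* recoverable
from the closed form at that column's lag sum (2.182 gives 1.07); the
package reports the formula's value and the discrepancy is documented
rather than patched. Similarly, the printed specification intercepts are
not recoverable from the stated calibration (the covariate and
fixed-effect means that enter them are unpublished), which is why $\bar h$
is always re-derived.

Report-table rounding is half-away-from-zero (`round_half_up()`), matching
the printed precision (1 d.p. for scenario tables, 2 d.p. for response
coefficients).

## Carbon dynamics

Annual CO2 growth follows a stationary AR(3),
$c_t = \rho_0 + \sum_j \rho_j c_{t-j} + \xi_t$, with reference coefficients
$(0.2598,\,0.2149,\,0.3212)$ and innovation sd $\sigma_\xi = 0.544$ % p.a.
The intercept follows the identity $\rho_0 = (1-\sum_j\rho_j)\,\mu_c$
(the printed per-order intercepts are inconsistent with that identity and
are not used). Stationary moments come from the closed-form Yule–Walker
system (`stationary_moments()`), cross-checked in the test suite against
long-simulation oracles. Stationarity is decided by companion-matrix
eigenvalues, not the (merely sufficient) condition $\sum_j|\rho_j|<1$.

One numerical subtlety: at the reference coefficients the Yule–Walker
stationary sd is 0.729 % p.a., while the 1960–2022 record's sd — and the
published simulated sd band [0.66, 0.71] — is 0.680. The original
simulations were evidently calibrated to the *record's* two moments, so
the package's baseline simulator, `baseline_carbon_ar()`, keeps the AR
coefficients and rescales $\sigma_\xi$ so the stationary sd is exactly
0.680. With that convention the reimplementation's cross-run incidence
mean falls inside the published one-way Gaussian band [6.7, 7.8] %.

Shock families: Gaussian with sd $\sigma_\xi$, or logistic with location 0
and scale $s=\sigma_\xi$. The logistic parameterisation is the simplest
reading consistent with the published logistic column showing roughly
doubled sd (a logistic with scale $s$ has sd $s\pi/\sqrt3 \approx 1.81 s$)
and positive excess kurtosis; the exact original parameterisation is
unstated, so this is a documented choice, not a reproduction target.

## Monte-Carlo engine and its conventions

`simulate_incidence()` pushes simulated carbon paths through the transfer:
per run (default 2000 runs of 2000 years after a 500-year burn-in) it
records the trajectory's mean, sd, skewness and kurtosis, and reports
cross-run 95 % *percentile* intervals (the published bracketed bands are
across runs; the original interval convention is unstated — percentile
intervals are the assumption least sensitive to distributional shape).

The persistence term $\delta$ admits three treatments:

* `"probability"` (default): $\delta$ multiplies the previous period's
  simulated probability — a deterministic recursion initialised at
  $\bar\mu_p$, giving smooth incidence trajectories. At the baseline
  calibration its fixed point is exactly the 6.2 % target.
* `"state"`: a Bernoulli state is drawn each period (the observable-state
  analogue used in estimation).
* `"fixed"`: the term is frozen at the calibration-point lagged incidence.
  This is the convention used by scenario evaluation, where *every*
  non-carbon term is held at its calibration value; it is the only choice
  under which the degenerate $\sigma_c = 0$ scenario run equals the
  scenario certainty equivalent exactly, keeping the simulated and
  closed-form columns of the scenario table mutually consistent. (Under
  the recursive mode the $\sigma_c=0$ fixed point self-equilibrates
  slightly below the certainty equivalent whenever the scenario mean is
  below baseline.)

The urban-share control is held fixed at its calibration mean during
simulation (the simulated covariate path is unspecified in the source
analysis, and since calibration absorbs the term into $\bar h$, its level
does not affect wedge dynamics).

The beta benchmark (`fit_beta_benchmark()`) is moment-matched to the
historical incidence mean 6.2 % and sd 5.6 % ($\alpha \approx 1.088$,
$\beta \approx 16.46$); `rmse_vs_beta()` compares sorted simulated
trajectories against sorted equal-length beta samples (quantile matching —
the original pairing is undefined, and quantile matching is the standard
distribution-comparison choice that makes the self-comparison limit vanish).

## Scenario evaluation

`scenario_spec()` carries the canonical 2023–2100 mean growth rates per
RCP pathway (0.19, 0.34, 0.56, 0.91, 1.54 % p.a.);
`mean_growth_from_endpoint()` derives custom means from a 2100 ppm level
by continuous compounding. `scenario_simulation()` retargets the AR
template's intercept and innovation sd so the stationary moments equal the
scenario's $(\mu_c, \sigma_c)$ — coefficients untouched, since only the two
moments are varied — and simulates under the baseline (0.68) and
stabilized (0.30 % p.a.) variability regimes.
`decarbonisation_gradient()` computes the discrete dividends
$\Delta\bar\mu_p/\Delta\mu_c$ and $\Delta E[\tilde\mu_p]/\Delta\mu_c$
against a reference pathway from *unrounded* internal values; only the
RCP4.5-vs-RCP2.6 certainty-equivalent entry ($\approx 1.7$) is robust to
the unknown original rounding stage, and it is the only one asserted.

## The synthetic-data generator

`generate_panel()` emulates the structure of the EM-DAT/World-Bank inputs:
200 countries over 1960–2022 (the real panel spans 158–218 entities),
binary events drawn from the logistic model under Normal$(0, 0.5)$ country
effects on the log-odds scale, a deterministic per-country logistic
urban-share growth curve bounded in $(0,1)$, lagged-state dynamics, and a
shared AR(3) carbon forcing. The intercept is calibrated by root finding
on the exact two-state probability recursion so the *implied* pooled
incidence is 6.2 %; realised pooled incidence then differs only by
sampling noise (about $\pm 0.2$ pp at the default size). Choices a
maintainer should know:

* country-effect sd $\tau = 0.5$ — the source estimates, never simulates,
  its fixed effects, so their dispersion is a package choice; 0.5 log-odds
  gives a realistic cross-country incidence spread (roughly 3–12 % across
  the central 90 % of countries) without making any country degenerate;
* the urban-share curve is deterministic (ceiling 0.55–0.95, rate
  0.02–0.08/yr, midpoint 1975–2005) so the only randomness is in shocks
  and event draws;
* generators are pure functions of `(spec, seed)`.

What a green test on synthetic data does **not** establish: the generator
has none of EM-DAT's reporting biases — no under-reporting thresholds, no
multi-country events, no secular reporting improvements — so recovery
results certify the estimator, not the provenance of the historical
coefficients.

## Numerical choices and degenerate inputs

* `logistic_transfer()` splits by sign to avoid overflow at large
  $|x|$; finite-input checks reject NA/Inf explicitly.
* Intercept calibration is exact (closed form), round-tripping to 1e-12.
* Perfect separation: countries (and under two-way FE, years) whose
  outcomes never vary are excluded before fitting — their dummies are
  unidentified — and reported via `n_obs`; single-class outcomes raise an
  error. With two-way effects the *global* carbon lags lie in the span of
  the year dummies, so some trailing dummies are aliased; the carbon terms
  are listed first and stay identified up to that normalisation (the
  standard dummy-variable treatment).
* The dummy-variable estimator carries incidental-parameter bias at short
  panels; this is accepted and documented, matching the original
  description (no conditional-logit reduction by default). The bias is
  most visible on the lagged-state (persistence) coefficient: with pooled
  incidence near 6 %, a country records only ~3–4 events over six decades,
  and the within-country transitions that identify $\delta$ are so few that
  the dummy-FE estimate is attenuated heavily toward zero (the Nickell-type
  dynamic-panel bias, amplified by rare outcomes — the test suite measures
  and reports the attenuation). The lag elasticities and the control, whose
  identification is mostly cross-sectional/common-shock, are far less
  affected. Confidence-interval coverage of the ML estimator is therefore
  certified on a correctly specified homogeneous panel (no incidental
  parameters), while the FE operating point is held to sign recovery and
  out-of-sample AUROC.
* Doubling time is $\lceil \log 2 / \log(1+g)\rceil$; $g \le 0$ errors.
* AR estimation is conditional ML (least squares on the lagged design);
  the bootstrap is iid, matching the original caption's wording (an iid
  bootstrap *undercovers* for persistent series — its CIs are reported as
  resampling intervals, not model-based ones).

## Known limitations

* Exact reproduction of the published stochastic tables is not attempted:
  whether the original simulations include the urban term and the
  persistence recursion, and the original CI convention, are unstated.
  Those bands are checked qualitatively and reported, not hard-asserted.
* Two-way fixed effects with a global regressor is an identification
  compromise (see above); treat the two-way elasticities as
  normalisation-dependent.
* No temperature or damage modelling, no extreme-value shock families, no
  GEE or interactive fixed effects.
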