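# carbonwedge

Climate-disaster incidence risk from stochastic CO2 concentration growth.

## What it does, and for whom

`carbonwedge` is for researchers and risk analysts who want to quantify how
fluctuations in atmospheric CO2 concentration translate into the annual
likelihood of climate-related disasters (floods, storms, droughts,
wildfires, heatwaves). It implements a complete analysis pipeline around a
logistic (logit) transfer model linking one-year-ahead disaster incidence
in a country-year panel to present and lagged global CO2 growth:

$$
p_{t+1} \;=\; \Lambda\Big(\bar h + \textstyle\sum_{j=0}^{P} h_j\,c_{t-j}
 + \gamma \log X_{it} + \delta\,p_{it} + \delta^c_i + \delta^g_t\Big),
\qquad \Lambda(x)=\frac{e^x}{1+e^x},
$$

with $c_t = 100\,\Delta\log C_t$ the annual CO2 growth (percent p.a.),
$X_{it}$ the urban population share, $\delta$ the persistence of incidence
and country/year fixed effects. Carbon growth itself follows a stationary
AR(3), $c_t = \rho_0 + \sum_j \rho_j c_{t-j} + \xi_t$, whose stationary
moments come from the closed-form Yule–Walker equations.

Because $\Lambda$ is convex at the calibrated operating point
($\bar\mu_p \approx 6.2\%$), expected incidence under stochastic carbon
growth exceeds the certainty equivalent by a positive **uncertainty wedge**
$UW_p = E[\tilde p] - \bar\mu_p$ (Jensen's inequality), which widens with
both the mean and the variance of CO2 growth. The package decomposes total
disaster risk into these two parts and evaluates IPCC RCP concentration
pathways under baseline (0.68 % p.a.) and stabilized (0.30 % p.a.) carbon
growth variability.

Modules: logistic-transfer mathematics (`logistic_transfer`,
`certainty_equivalent`, `calibrate_intercept`, `cumulative_response`,
`doubling_time`), AR carbon dynamics (`fit_ar`, `stationary_moments`,
`simulate_carbon`, `bootstrap_moments`), dynamic panel logit estimation
with AUROC (`build_design`, `fit_panel_logit`, `auroc`), a Monte-Carlo
engine (`simulate_incidence`, `expected_wedge`, `fit_beta_benchmark`,
`rmse_vs_beta`, `convexity_percentile_run`), RCP scenario evaluation
(`scenario_simulation`, `decarbonisation_gradient`), a synthetic-data
generator emulating EM-DAT/NOAA-style inputs (`generate_panel`,
`generate_carbon_history`, `write_fixtures`), and a CLI (`run_pipeline`).

## Worked example

```r
library(carbonwedge)

# 1. calibrate the one-way FE (urban control) elasticities to the
#    historical operating point: mean CO2 growth 1.624 % p.a., pooled
#    incidence 6.2 %
params <- reference_logit_params("one_way_urban")
point  <- baseline_point(params, p_bar = 0.062)
params <- calibrate_params(params, point, target = 0.062)

# 2. simulate stochastic incidence: 2000 runs x 2000 years of AR(3)
#    carbon growth pushed through the logistic transfer
sim <- simulate_incidence(simulation_config(params, baseline_carbon_ar(),
                                            runs = 2000, horizon = 2000,
                                            seed = 1))
sim
#> Simulated disaster incidence: 2000 runs x 2000 years ( gaussian shocks )
#>   certainty equivalent  : 6.20 %
#>   mean E[mu_p]          : 7.67 %  95% CI [6.7, 8.7]
#>   uncertainty wedge     : 1.47 %  95% CI [0.5, 2.5]
#>   sd / skew / kurt CIs  : [4.4, 6.7] % / [1.3, 2.7] / [4.9, 14.8]

# 3. certainty-equivalent incidence along the five RCP pathways
ce <- vapply(rcp_scenarios(), scenario_certainty_equivalent, numeric(1),
             params = params)
round_half_up(ce, 1)
#> RCP2.6 RCP3.4 RCP4.5   RCP6 RCP8.5
#>    1.0    1.2    1.6    2.5    5.6

# 4. disaster-count projection from the two-way FE elasticities and the
#    2015-2022 CO2 rise (4.4 %)
response_report(sum(reference_logit_params("two_way_urban")$lag_coeffs),
                0.01624, co2_rise_pct = 4.4)
#> Response d ln mu_p / d mu_c : 1.11
#> Disaster-count growth       : 4.88 % p.a.
#> Doubling time               : 15 years (1.71 -> 3.42 events/country-year)
```

Reading the output: expected stochastic incidence (7.67 %) exceeds the
certainty equivalent (6.2 %) by a 1.5-point uncertainty wedge — the share
of disaster risk attributable purely to carbon-growth uncertainty. Cutting
mean CO2 growth from the RCP8.5 pathway (5.6 % incidence) to RCP2.6
(1.0 %) removes most certainty-equivalent risk; stabilising carbon growth
(halving $\sigma_c$) additionally collapses the wedge toward zero. Under
the strongest estimated convexity, the disaster count doubles in 15 years.

## Command line

```sh
Rscript inst/cli/carbonwedge.R make-synthetic --output fixtures --seed 1
Rscript inst/cli/carbonwedge.R fit-ar    --input fixtures/carbon.csv --order 3
Rscript inst/cli/carbonwedge.R fit-logit --input fixtures/panel.csv \
        --carbon fixtures/carbon.csv --fe one --output coefs.csv
Rscript inst/cli/carbonwedge.R simulate  --runs 2000 --years 2000 --seed 1
Rscript inst/cli/carbonwedge.R scenarios --sigma baseline --output rcp.csv
```

All tables are comma-separated text with a `#` metadata header recording
the package version, seed and a config hash, so every output regenerates
byte-identically from its recorded configuration.

## Further reading

The methods vignette (`vignettes/carbon-disaster-risk.Rmd`) documents the
model and its assumptions, unit and calibration conventions, the
Monte-Carlo and scenario conventions, what the synthetic-data generator
does and does not emulate, and known limitations.
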