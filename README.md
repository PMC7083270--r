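# washsim

Country-level simulation of access to improved and piped drinking water,
WASH-related mortality (deaths attributable to inadequate water, sanitation
and hygiene), household water-collection time, and the economic losses these
impose, projected annually to 2050 with Monte Carlo uncertainty
propagation. The package is aimed at burden-of-disease and development
economists who need a transparent, fully testable implementation of the
semi-elasticity forecasting approach used for sub-Saharan Africa — and a
synthetic-data generator that makes every stage verifiable without access
to the underlying JMP/UN/WHO/World Bank compilations.

## The model

Three panel regressions give the semi-elasticities (outcomes in natural
units against log income):

- coverage (improved or piped, fraction):
  `Coverage_it = κ0 + κ_Y ln(Y_i,t−1) + κ_urban Urban_it + κ'Z_it + δ_it + μ_i`
- WASH mortality (deaths/1,000/yr):
  `d_it = α0 + α_Y ln(Y_it) + β_imp Improved_it + β_piped Piped_it + γ'X_it + δ_it + ε_i`
- one-way collection time (minutes):
  `t_it = θ0 + θ_Y ln(Y_it) + γ_urban Urban_it + γ'X_it + δ_it + ε_i`

fit by pooled least squares with country-clustered standard errors
(one-way random effects available behind a flag). The fitted coefficients
drive annual forward recursions from each country's last observed year,
with exogenous GDP, population, urbanisation and temperature paths:

```
Coverage_it = Coverage_i,t−1 + κ_Y Δln Y_it + κ_urban ΔUrban_it
d_it        = d_i,t−1 + α_Y Δln Y_it + β_imp ΔImp_it + β_piped ΔPiped_it + γ_temp ΔT_it
t_it        = t_i,t−1 + θ_Y Δln Y_it + γ_urban ΔUrban_it
deaths_it   = d_it / 1000 × Pop_it
```

GDP growth is optionally temperature-adjusted (`g + coeff × ΔT`). Economic
losses are `Losses_it = H_it + T_it` with health losses
`H_it = Pop_it · d_it/1000 · VSL_it · (1 + f_morb)` (VSL by power-law
benefit transfer in income; morbidity as a fixed fraction of mortality
losses, base 0.25) and time losses
`T_it = Pop_it/hhsize_it · 2 trips · t_it/60 · v_it · days`, where the
hourly value of time `v_it` is a fraction of bottom-80% per-capita income.
Monte Carlo draws per-country growth from N(3.7%, 1.3%) and the
elasticities from their 95% confidence intervals (1,000 realisations by
default), summarized as pointwise interquartile bands and a variance
decomposition by squared standardized regression coefficients. Countries
are classified into four mortality-trajectory groups from their baseline
and 2050 rates and aggregated with population weights.

## Worked example

```r
library(washsim)

cfg      <- synth_config(n_countries = 20, years = 1990:2009, seed = 2026)
panel    <- generate_panel(cfg)                  # synthetic country-year panel
fit      <- wash_fit(panel)                      # the three panel regressions
round(coef(fit)[c("kappa_Y_improved", "alpha_Y", "beta_imp", "theta_Y")], 4)
#> kappa_Y_improved          alpha_Y         beta_imp          theta_Y
#>           0.0501          -0.5073          -2.1020          -1.0878

paths     <- generate_scenario_inputs(cfg)       # exogenous paths to 2050
valuation <- valuation_config(vsl_ref = 1e5, y_ref = 2000)
dists     <- parameter_distributions(
  elasticities = elasticity_dists(fit, c("kappa_Y_improved", "kappa_Y_piped",
                                         "alpha_Y", "beta_imp", "beta_piped")),
  n_draws = 200)
result <- run_pipeline(panel, paths, valuation, dists = dists, seed = 2026)

table(result$groups$group)                       # trajectory groups
#>  1  2
#>  9 11
subset(result$aggregates$mortality_rate, year %in% c(2009, 2030, 2050))
#>    group year     value population
#> 1      1 2009 2.6058571  425655582
#> 22     1 2030 2.1226154  719553246
#> 42     1 2050 1.6623851 1186342741
#> 43     2 2009 1.9848871  477160440
#> 64     2 2030 1.1652039  806620088
#> 84     2 2050 0.4432653 1329891697
```

Group 1 here starts at 2.6 WASH deaths per 1,000 per year and is still at
1.7 in 2050 under growth-driven trends, while group 2 falls from 2.0 to
0.44 — the slow-versus-steady divergence the grouping is designed to
surface. The Monte Carlo interquartile band on the region-wide
(population-weighted) mortality rate:

```r
round(result$ensemble$quantiles$mortality_rate[, c("2030", "2050")], 3)
#>      2030  2050
#> q25 1.634 1.028
#> q50 1.662 1.086
#> q75 1.694 1.147

vd <- variance_decomposition(
  result$ensemble$draws,
  result$ensemble$outputs$mortality_rate[, length(result$ensemble$years)])
```

With only 20 synthetic countries, per-country growth draws dominate the
2050 variance (each contributing 2–11%), with the mortality elasticities
(`beta_piped`, `alpha_Y`, `beta_imp`) contributing a few percent each and a
residual share of 0.7% — the decomposition is nearly exhaustive because
the simulator is nearly linear in its parameters.

See `vignettes/washsim-methods.Rmd` for the model assumptions, parameter
defaults and their rationale, and known limitations.

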