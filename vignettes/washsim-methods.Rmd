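---
title: "Methods: forecasting WASH mortality, water access and economic losses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forecasting WASH mortality, water access and economic losses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(washsim)
```

## The problem and the model

Inadequate access to safe drinking water still causes substantial
mortality — mainly diarrhoeal disease in young children — and absorbs
hours of household time fetching water, predominantly in sub-Saharan
Africa. washsim forecasts, country by country to a configurable horizon
(default 2050), four linked outcomes: coverage with *improved* water
sources and with *piped water on premises* (the piped definition is a
nested subset of improved), the WASH-attributable mortality rate (deaths
per 1,000 per year) and the annual death count, average one-way
water-collection time, and the economic losses attached to these outcomes.

The approach is deliberately reduced-form. Three panel regressions link
each outcome to national income and urbanisation:

* coverage on ln(*lagged* GDP per capita) and urban share — income enters
  with a one-period lag because infrastructure responds to resources
  already earned;
* the mortality rate on ln(GDP per capita), improved coverage, piped
  coverage and (optionally) temperature;
* collection time on ln(GDP per capita) and urban share.

Because the outcomes stay in natural units while income enters in logs,
every fitted coefficient is a *semi-elasticity*: the change in the outcome
per unit change in ln income. The fits are associations used for
trend extrapolation; no causal identification is attempted or implied.

The fitted coefficients then drive first-order annual recursions from each
country's last observed year (see `?run_projection` for the exact update
equations). The recursions propagate *changes* in the drivers, so any
country-specific level differences absorbed by controls or error
components in the fits drop out of the forecast — only the slope
coefficients matter downstream.

## Estimation choices

The written error structure of the regressions has a time-varying
disturbance plus a country-level component. Two estimators honour it:

* **pooled least squares with country-clustered robust standard errors**
  (`sandwich::vcovCL`, HC1, t critical values with clusters − 1 degrees of
  freedom) — the default, robust to arbitrary within-country correlation;
* **one-way random effects** (`lme4::lmer`, random country intercept) —
  behind `estimator = "re"`.

The default is the pooled estimator because it makes no distributional
assumption about the country component and its confidence intervals feed
directly into the Monte Carlo stage. Coverage is fit in fraction units
without transformation; near its bounds a linear model can predict outside
[0, 1], which the projection stage handles by clipping (below). Controls
(regional dummies, trends, governance, survey-source indicators, ...) are
accepted as arbitrary named columns rather than hard-coded, since the
synthetic panels used for validation have no fixed region structure.
Incomplete rows are dropped listwise with a reported count; the panels
this emulates have no documented imputation rule, so none is invented.

## The synthetic-data generator

`generate_panel()` emulates the country-year compilations the model is
designed for (coverage tables, demographic projections, burden-of-disease
mortality, survey collection times) with *known* structural coefficients,
so estimation, projection and the Monte Carlo machinery can be validated
end to end. Study conditions are fixed by the defaults: 40 countries
observed 20 years; initial GDP per capita uniform on [500, 3000] (1990
international dollars) with per-country log growth N(0.037, 0.013) — the
same distribution the Monte Carlo stage samples; initial urban share
uniform on [0.20, 0.50] drifting +0.005/yr; population 1–50 million
growing 2.5%/yr; a +0.02 °C/yr temperature ramp. Default structural
coefficients put outcomes in realistic ranges (improved coverage
0.4–0.7, piped 0.1–0.3, mortality ≈1–3.5 deaths/1,000, collection times
≈30–37 minutes) while keeping the linear indices away from their bounds,
so clipping stays inactive on noise-free panels and exact parameter
recovery is well defined. Noise is Gaussian and homoskedastic per
equation (coverage 0.02, mortality 0.10 deaths/1,000, time 2 minutes) —
the simplest form consistent with additive errors.

Two deliberate simplifications: controls (fertility, literacy) are drawn
independently of the outcomes, and there is no spatial correlation between
countries. Passing tests on these panels therefore demonstrates the
machinery is correct, not that real-world confounding or cross-country
dependence is handled; with real data the elasticities themselves would
also come with companion-study specification choices this package does not
reproduce.

One generator design point departs from the obvious construction. Drawing
piped coverage as improved × a random sub-share guarantees nesting but
destroys the linear structure that lets a fit recover the piped
coefficients exactly — a product of a linear index and a Beta draw is not
linear in ln GDP. The default therefore draws piped coverage from its own
linear index, with coefficients placed so it stays strictly below improved
across the realistic range, then caps it at improved. The sub-share
construction remains available (`piped_mode = "subshare"`) for stress
tests of the nesting invariant.

## Projection: units, bounds, temperature

The recursions propagate Δln(GDP per capita), not level changes, because
the regression coefficients are per log-unit of income; driving them with
dollar changes would be dimensionally inconsistent. The literal
level-change reading is preserved behind `dy_mode = "level"`.

Unbounded linear recursions can leave feasible ranges, and no bound
handling is prescribed by the forecasting equations themselves. The
package clips coverage to [0, 1] and floors mortality and collection time
at 0 *after each annual step*, then caps piped at improved coverage (the
definitions are nested). Each bound event is counted and surfaced
(`attr(projection, "n_clipped")`, per-row in the artifacts) so that
clipping is an auditable modelling decision, not silent behaviour. All
bound handling can be switched off (`clip = FALSE`) to recover the exact
closed form — under constant drivers each recursion equals baseline +
k × (per-step change), which the test suite verifies to 12 significant
digits over randomized parameter sets.

Temperature enters twice: annual GDP growth is shifted by
`climate_gdp_coeff × ΔT` (central/upper/lower estimates are scenario
inputs, default 0), and the mortality recursion carries `γ_temp ΔT`. The
temperature–mortality coefficient typically comes from external
epidemiological literature rather than the panel fits; when the panel has
no usable temperature column, the fit flags `gamma_temp` as external and
the scenario must supply it. Both improved and piped deltas enter the
mortality recursion as written, although piped is a subset of improved;
the overlap between the two terms is a property of the source regressions
that the projection passes through unchanged.

The baseline year is each country's latest observed panel year, and the
observed row is carried in the output (flagged `observed`) so plots can
shade the observed period.

## Economic valuation

Health losses value projected deaths at a value of statistical life (VSL)
transferred across incomes by a power law,
`VSL = vsl_ref (y / y_ref)^η`, with η defaulting to 1. The reference pair
(`vsl_ref`, `y_ref`) is required configuration with no default: it sets
the currency level of every loss figure and belongs to the analyst's
valuation framework, not to this package. Morbidity losses are a fixed
fraction of mortality losses (`f_morb`, base 0.25, sensitivity range
0.10–0.40) because country-level incidence data are not modelled. Time
losses value `population/household size` households × 2 one-way trips/day
× one-way minutes/60 × 365 days at an hourly opportunity cost equal to a
fraction (default 0.5) of bottom-80% per-capita income
(`share_b80 × GDP / 0.8`, since the bottom 80% hold `share_b80` of GDP
and 80% of the population) spread over 2,000 work hours/year. The 0.5 and
2,000 defaults are implementation choices, flagged as such in the
documentation. Income shares and household sizes are held at their
baseline values over the horizon — the panel sources provide no
projections for them. All losses are annual flows in constant currency;
no discounting is applied.

## Monte Carlo design

Each realisation draws: one average annual growth rate per country from
N(3.7%, 1.3%) (held constant over the horizon within a draw, independent
across countries — negative draws are allowed, the distribution's negative
mass being negligible); each selected elasticity from a normal centred on
its point estimate with sd = CI width / (2 × 1.96), truncated to the 95%
CI (sampling stays sign-agnostic whenever the CI crosses zero); the
morbidity fraction uniform on [0.10, 0.40]; and optionally the
climate-growth coefficient between its literature bounds. Families are
configurable per parameter (fixed, normal, uniform, triangular) since the
exact distribution assignments used with real data are not fixed by the
method. Sampling uses inverse-CDF draws so every family consumes the same
uniform stream — the draw matrix depends only on the seed, not on which
families are selected.

The default 1,000 realisations rerun projection and losses per draw;
outputs are aggregated per year (population-weighted mortality rate and
collection time, summed deaths and losses) and summarized by pointwise
per-year quantiles (25/50/75 by default). Pointwise bands answer "how
uncertain is the year-2050 value"; they are not joint trajectory bands. A
failing draw is recorded and skipped with a warning.

Variance decomposition regresses a draw-level output on the draw matrix
and reports squared standardized regression coefficients. For a
near-linear simulator these shares sum to the regression R² (≤ 1, equal
to 1 for an exactly linear model up to finite-sample parameter
correlation); the residual share 1 − R² is reported alongside. SRC² is
the standard first-order attribution for near-linear simulators; no
Sobol-type indices are computed.

## Trajectory grouping

Countries are grouped by (baseline rate, terminal rate), both in
deaths/1,000: group 1 starts at or above 1.0 and remains at or above 1.0
at the terminal year; group 3 starts in [0.5, 1.0) and falls below 0.1;
group 4 starts below 0.5; group 2 is the remainder (moderate with slow
decline). The thresholds (0.5, 1.0, 0.1, 1.0) encode the narrative
archetypes — high/persistent, moderate/slow, moderate/eliminating,
low/low — and are fully configurable because no formal rule accompanies
the narrative. Classification uses the base-case trajectory, not ensemble
quantiles. Group aggregates are population-weighted means for rates and
times, totals for deaths, losses and population. A bundled reference
table (`inst/extdata/ssa_groups_reference.csv`) lists the published
group membership for sub-Saharan countries; one country (Zimbabwe)
appears in two group lists in the source narrative and is kept twice with
a note rather than silently resolved.

## Numerical and interface choices

* Calendar-year steps; the lag in the coverage equation is exactly one
  panel period.
* Coverage is stored as fractions internally; `read_panel()` converts
  percent columns at the boundary.
* Mortality is stored as deaths per 1,000 per year; the deaths and loss
  formulas convert explicitly (`rate/1000 × population`).
* Panel CSVs are written with 17 significant digits so a write/read round
  trip reproduces every field.
* All randomness flows from integer seeds; `run_pipeline()` fans a single
  top-level seed out to named substreams.
* Problem sizes in the test suite (40 countries × 20 years, 200
  replicates for CI-coverage checks, 1,000 randomized recursion cases,
  10,000-draw variance-decomposition benchmark) were chosen as the
  smallest designs at which the stochastic checks have comfortable
  resolution.
* This package provides functions, not a shell tool: `run_pipeline()` and
  `render_report()` are the entry points, and all artifacts are plain CSV
  and JSON.

## Known limitations

The recursions extrapolate historical associations; they cannot represent
structural breaks, policy shocks, or catastrophic events (floods,
droughts, conflict). Coverage fits near the [0, 1] bounds rely on
clipping rather than a bounded link function. The morbidity fraction is a
shortcut for unmodelled incidence. Growth draws are independent across
countries, ignoring regional co-movement, which likely *understates*
ensemble spread for region-level aggregates. Aesthetic and
quality-of-life benefits of water access are not valued. And with real
data, the elasticities depend on specification choices (regions, trends,
interactions) made outside this package; everything downstream is
conditional on them.
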