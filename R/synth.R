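# Synthetic country-year panels with known semi-elasticities, and smooth
# exogenous projection paths. Everything downstream (estimation, projection,
# losses, Monte Carlo, grouping) is testable against the generator's truth
# without any external data.

#' Default generator truth
#'
#' The structural semi-elasticities used by [generate_panel()] unless
#' overridden. Magnitudes are chosen to put outcomes in realistic
#' sub-Saharan-Africa ranges: improved coverage roughly 0.4-0.7, piped
#' coverage 0.1-0.3, WASH mortality roughly 1-3.5 deaths per 1,000 per year,
#' one-way collection times around 30-37 minutes.
#'
#' @return An [elasticity_set()].
#' @export
default_true_elasticities <- function() {
  elasticity_set(
    kappa0_improved = 0.10, kappa_Y_improved = 0.05,
    kappa_urban_improved = 0.20,
    kappa0_piped = -0.10, kappa_Y_piped = 0.03, kappa_urban_piped = 0.15,
    alpha0 = 8.0, alpha_Y = -0.5, beta_imp = -2.0, beta_piped = -3.0,
    gamma_temp = 0.05,
    theta0 = 45, theta_Y = -1.0, gamma_urban = -10
  )
}

#' Configure the synthetic-panel generator
#'
#' @param n_countries Number of countries.
#' @param years Inclusive integer vector of calendar years (the panel span).
#' @param true_elasticities [elasticity_set()] of structural coefficients;
#'   see [default_true_elasticities()].
#' @param gdp0_range Range (length 2, positive) of initial GDP per capita.
#' @param growth_mean,growth_sd Mean and sd of the per-country annual log
#'   GDP growth rate. Defaults 0.037 and 0.013 match the historical
#'   distribution of sub-Saharan growth used in the Monte Carlo stage.
#' @param pop0_range Range of initial population (persons).
#' @param pop_growth Annual exponential population growth rate.
#' @param pop_model `"exponential"` or `"logistic"` population path for
#'   [generate_scenario_inputs()] (logistic saturates at 4x the initial
#'   population).
#' @param urban0_range Range (within \[0, 1\]) of initial urban share.
#' @param urban_drift Annual additive drift of urban share (capped at 1).
#' @param temp_ramp Annual increase in the temperature anomaly (degrees C
#'   per year).
#' @param noise_sd Named list of Gaussian error standard deviations for the
#'   three outcome equations: `coverage` (fraction), `mortality`
#'   (deaths/1,000), `time` (minutes). Zero gives exact structural panels.
#' @param piped_mode `"structural"` (default) draws piped coverage from its
#'   own linear index and caps it at improved coverage; `"subshare"` draws
#'   piped as improved times a Beta(8, 12) sub-share (guarantees nesting but
#'   is not linear in ln GDP, so fits cannot recover the piped
#'   coefficients).
#' @param seed Integer RNG seed; identical configs generate identical
#'   panels.
#' @return A validated config of class `synth_config`.
#' @export
synth_config <- function(n_countries = 40,
                         years = 1990:2009,
                         true_elasticities = default_true_elasticities(),
                         gdp0_range = c(500, 3000),
                         growth_mean = 0.037,
                         growth_sd = 0.013,
                         pop0_range = c(1e6, 5e7),
                         pop_growth = 0.025,
                         pop_model = c("exponential", "logistic"),
                         urban0_range = c(0.20, 0.50),
                         urban_drift = 0.005,
                         temp_ramp = 0.02,
                         noise_sd = list(coverage = 0.02, mortality = 0.10,
                                         time = 2.0),
                         piped_mode = c("structural", "subshare"),
                         seed = 1L) {
  stopifnot(n_countries >= 1, length(years) >= 2)
  pop_model <- match.arg(pop_model)
  piped_mode <- match.arg(piped_mode)
  rng_ok <- function(r, lo = -Inf, hi = Inf) {
    length(r) == 2 && r[1] <= r[2] && r[1] >= lo && r[2] <= hi
  }
  if (!rng_ok(gdp0_range, lo = 0) || gdp0_range[1] <= 0) {
    stop("gdp0_range must be a nonempty positive interval", call. = FALSE)
  }
  if (!rng_ok(urban0_range, 0, 1)) {
    stop("urban0_range must be a nonempty interval within [0, 1]",
         call. = FALSE)
  }
  if (!rng_ok(pop0_range, lo = 0) || pop0_range[1] <= 0) {
    stop("pop0_range must be a nonempty positive interval", call. = FALSE)
  }
  noise_sd <- utils::modifyList(
    list(coverage = 0.02, mortality = 0.10, time = 2.0), as.list(noise_sd))
  if (any(unlist(noise_sd) < 0) || growth_sd < 0) {
    stop("noise_sd and growth_sd must be >= 0", call. = FALSE)
  }
  stopifnot(inherits(true_elasticities, "elasticity_set"))
  structure(list(n_countries = as.integer(n_countries),
                 years = as.integer(sort(years)),
                 true_elasticities = true_elasticities,
                 gdp0_range = gdp0_range, growth_mean = growth_mean,
                 growth_sd = growth_sd, pop0_range = pop0_range,
                 pop_growth = pop_growth, pop_model = pop_model,
                 urban0_range = urban0_range, urban_drift = urban_drift,
                 temp_ramp = temp_ramp, noise_sd = noise_sd,
                 piped_mode = piped_mode, seed = as.integer(seed)),
            class = "synth_config")
}

# Per-country exogenous draws shared by panel and scenario generation.
synth_countries <- function(config) {
  n <- config$n_countries
  data.frame(
    country_id = sprintf("C%02d", seq_len(n)),
    gdp0 = stats::runif(n, config$gdp0_range[1], config$gdp0_range[2]),
    growth = stats::rnorm(n, config$growth_mean, config$growth_sd),
    pop0 = stats::runif(n, config$pop0_range[1], config$pop0_range[2]),
    urban0 = stats::runif(n, config$urban0_range[1], config$urban0_range[2]),
    income_share_b80 = stats::runif(n, 0.30, 0.60),
    household_size = stats::runif(n, 4, 6),
    ctrl_fertility = stats::runif(n, 2.5, 6.5),
    ctrl_literacy = stats::runif(n, 0.3, 0.95),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic country-year panel
#'
#' Exogenous drivers: GDP per capita grows at a per-country constant log
#' rate from a uniform initial level; urban share drifts linearly (capped at
#' 1); population grows exponentially; the temperature anomaly ramps
#' linearly from 0. Outcomes follow the structural equations whose
#' coefficients the estimation stage is designed to recover:
#'
#' * improved coverage: linear in ln(previous-year GDP) and urban share;
#' * piped coverage: its own linear index (capped at improved), or a Beta
#'   sub-share of improved under `piped_mode = "subshare"`;
#' * WASH mortality: linear in ln(current GDP), improved coverage, piped
#'   coverage and temperature;
#' * one-way collection time: linear in ln(current GDP) and urban share.
#'
#' Gaussian noise with the configured standard deviations is added per
#' equation; coverage is then clipped to \[0, 1\] and mortality and
#' collection time floored at 0, so every generated record passes
#' [validate_panel()]. Controls (fertility, literacy) are independent
#' per-country draws, unrelated to the outcomes.
#'
#' @param config A [synth_config()].
#' @return A [wash_panel] with `n_countries * length(years)` records.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    cc <- synth_countries(config)
    tr <- coef(config$true_elasticities)
    years <- config$years
    t_idx <- seq_along(years) - 1L
    rows <- merge(cc, data.frame(year = years), by = NULL)
    rows <- rows[order(rows$country_id, rows$year), ]
    rows$t <- rows$year - years[1]
    rows$gdp_pc <- rows$gdp0 * exp(rows$growth * rows$t)
    rows$gdp_lag <- rows$gdp0 * exp(rows$growth * (rows$t - 1))
    rows$population <- rows$pop0 * exp(config$pop_growth * rows$t)
    rows$urban_share <- pmin(1, rows$urban0 + config$urban_drift * rows$t)
    rows$temperature <- config$temp_ramp * rows$t
    n <- nrow(rows)
    ns <- config$noise_sd
    imp <- tr["kappa0_improved"] + tr["kappa_Y_improved"] * log(rows$gdp_lag) +
      tr["kappa_urban_improved"] * rows$urban_share +
      stats::rnorm(n, 0, ns$coverage)
    rows$coverage_improved <- clip01(imp)
    if (config$piped_mode == "structural") {
      pip <- tr["kappa0_piped"] + tr["kappa_Y_piped"] * log(rows$gdp_lag) +
        tr["kappa_urban_piped"] * rows$urban_share +
        stats::rnorm(n, 0, ns$coverage)
      rows$coverage_piped <- pmin(clip01(pip), rows$coverage_improved)
    } else {
      share <- stats::rbeta(n, 8, 12)
      rows$coverage_piped <- rows$coverage_improved * share
    }
    mort <- tr["alpha0"] + tr["alpha_Y"] * log(rows$gdp_pc) +
      tr["beta_imp"] * rows$coverage_improved +
      tr["beta_piped"] * rows$coverage_piped +
      tr["gamma_temp"] * rows$temperature +
      stats::rnorm(n, 0, ns$mortality)
    rows$mortality_wash <- pmax(0, mort)
    ct <- tr["theta0"] + tr["theta_Y"] * log(rows$gdp_pc) +
      tr["gamma_urban"] * rows$urban_share + stats::rnorm(n, 0, ns$time)
    rows$collection_time <- pmax(0, ct)
    keep <- c(panel_columns(), "ctrl_fertility", "ctrl_literacy")
    wash_panel(rows[keep],
               metadata = list(source = "washsim synthetic generator",
                               seed = config$seed))
  })
}

#' Generate exogenous projection paths
#'
#' Smooth per-country paths of the exogenous drivers over a forecast
#' horizon, for use in a [scenario_config()]: GDP per capita at a constant
#' per-country log growth rate, population exponential or logistic
#' (saturating at four times the initial level), urban share with monotone
#' drift capped at 1, and a linear temperature ramp. With the same seed the
#' per-country levels and growth rates match [generate_panel()], so the
#' paths continue the panel.
#'
#' @param config A [synth_config()].
#' @param horizon Inclusive integer years of the projection (default: the
#'   year after the panel ends through 2050).
#' @return Data frame with columns `country_id`, `year`, `gdp_pc`,
#'   `population`, `urban_share`, `temperature`.
#' @export
generate_scenario_inputs <- function(config,
                                     horizon = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(horizon)) {
    horizon <- (max(config$years) + 1L):2050L
  }
  with_seed(config$seed, {
    cc <- synth_countries(config)
    rows <- merge(cc, data.frame(year = as.integer(horizon)), by = NULL)
    rows <- rows[order(rows$country_id, rows$year), ]
    rows$t <- rows$year - config$years[1]
    rows$gdp_pc <- rows$gdp0 * exp(rows$growth * rows$t)
    if (config$pop_model == "exponential") {
      rows$population <- rows$pop0 * exp(config$pop_growth * rows$t)
    } else {
      K <- 4 * rows$pop0
      rows$population <- K / (1 + (K / rows$pop0 - 1) *
                                exp(-config$pop_growth * rows$t))
    }
    rows$urban_share <- pmin(1, rows$urban0 + config$urban_drift * rows$t)
    rows$temperature <- config$temp_ramp * rows$t
    out <- rows[c("country_id", "year", "gdp_pc", "population",
                  "urban_share", "temperature")]
    rownames(out) <- NULL
    out
  })
}
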