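# Forward recursions: coverage, mortality and collection time stepped
# annually from the last observed values, driven by exogenous GDP,
# urbanisation and temperature paths. Income enters every recursion as the
# change in ln(GDP per capita), consistent with the semi-elasticity fits;
# `dy_mode = "level"` preserves the literal level-change reading.

#' Temperature-adjust an annual growth rate
#'
#' Adds the climate-growth association to an annual GDP growth rate:
#' `growth + coeff * delta_T`, with `coeff` in growth units per degree C of
#' annual warming.
#'
#' @param growth Annual (log) growth rate.
#' @param delta_T Temperature change over the year (degrees C).
#' @param coeff Change in annual growth per degree C (typically negative).
#' @return Adjusted growth rate(s).
#' @examples
#' adjust_gdp_growth(0.030, 0.5, -0.005)  # 0.0275
#' @export
adjust_gdp_growth <- function(growth, delta_T, coeff) {
  growth + coeff * delta_T
}

#' Project water coverage forward
#'
#' Annual recursion `cov_t = cov_{t-1} + kappa_Y * dlnY_t +
#' kappa_urban * dUrban_t`, clipped to \[0, 1\] after each step when
#' `clip = TRUE`.
#'
#' @param cov0 Starting coverage fraction in \[0, 1\].
#' @param dlnY Per-step changes in ln GDP per capita (vector, one per
#'   projected year).
#' @param dUrban Per-step changes in urban share (same length).
#' @param kappa_Y,kappa_urban Semi-elasticities from the coverage fit.
#' @param clip Apply the \[0, 1\] bounds each step (default `TRUE`).
#' @return Numeric series of length `length(dlnY)` with attribute
#'   `"n_clipped"` counting bound events.
#' @export
project_coverage <- function(cov0, dlnY, dUrban, kappa_Y, kappa_urban,
                             clip = TRUE) {
  stopifnot(length(dlnY) == length(dUrban), cov0 >= 0, cov0 <= 1)
  step_recursion(cov0, kappa_Y * dlnY + kappa_urban * dUrban,
                 lower = if (clip) 0 else -Inf,
                 upper = if (clip) 1 else Inf)
}

#' Project the WASH mortality rate forward
#'
#' Annual recursion `d_t = d_{t-1} + alpha_Y * dlnY_t + beta_imp * dImp_t +
#' beta_piped * dPiped_t + gamma_temp * dT_t`, floored at 0 after each step
#' when `floor = TRUE`. Rates are deaths per 1,000 persons per year.
#'
#' @param d0 Starting mortality rate (deaths/1,000), nonnegative.
#' @param dlnY,dImproved,dPiped,dT Per-step changes in ln GDP, improved
#'   coverage fraction, piped coverage fraction and temperature.
#' @param alpha_Y,beta_imp,beta_piped,gamma_temp Semi-elasticities.
#' @param floor Apply the zero lower bound each step (default `TRUE`).
#' @return Numeric series with attribute `"n_clipped"`.
#' @export
project_mortality <- function(d0, dlnY, dImproved, dPiped, dT,
                              alpha_Y, beta_imp, beta_piped,
                              gamma_temp = 0, floor = TRUE) {
  stopifnot(d0 >= 0,
            length(dlnY) == length(dImproved),
            length(dlnY) == length(dPiped),
            length(dlnY) == length(dT))
  step_recursion(d0, alpha_Y * dlnY + beta_imp * dImproved +
                   beta_piped * dPiped + gamma_temp * dT,
                 lower = if (floor) 0 else -Inf, upper = Inf)
}

#' Project one-way water-collection time forward
#'
#' Annual recursion `t_t = t_{t-1} + theta_Y * dlnY_t +
#' gamma_urban * dUrban_t`, floored at 0 after each step.
#'
#' @param t0 Starting one-way collection time (minutes), nonnegative.
#' @param dlnY,dUrban Per-step changes in ln GDP and urban share.
#' @param theta_Y,gamma_urban Semi-elasticities.
#' @param floor Apply the zero lower bound each step (default `TRUE`).
#' @return Numeric series with attribute `"n_clipped"`.
#' @export
project_collection_time <- function(t0, dlnY, dUrban, theta_Y, gamma_urban,
                                    floor = TRUE) {
  stopifnot(t0 >= 0, length(dlnY) == length(dUrban))
  step_recursion(t0, theta_Y * dlnY + gamma_urban * dUrban,
                 lower = if (floor) 0 else -Inf, upper = Inf)
}

# Shared stepping kernel: x_t = bound(x_{t-1} + increment_t).
step_recursion <- function(x0, increments, lower, upper) {
  out <- numeric(length(increments))
  x <- x0
  n_clipped <- 0L
  for (i in seq_along(increments)) {
    x <- x + increments[i]
    if (x < lower) { x <- lower; n_clipped <- n_clipped + 1L }
    if (x > upper) { x <- upper; n_clipped <- n_clipped + 1L }
    out[i] <- x
  }
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Deaths from a mortality rate and population
#'
#' `deaths = rate / 1000 * population`, the bridge from the per-1,000 rate
#' to annual person counts.
#'
#' @param rate Mortality rate (deaths/1,000/year), nonnegative.
#' @param population Persons, nonnegative.
#' @return Deaths per year.
#' @export
compute_deaths <- function(rate, population) {
  stopifnot(all(rate >= 0, na.rm = TRUE),
            all(population >= 0, na.rm = TRUE))
  rate / 1000 * population
}

#' Configure a projection scenario
#'
#' @param paths Data frame of exogenous per-country paths with columns
#'   `country_id`, `year`, `gdp_pc`, `population`, `urban_share`, and
#'   (optionally) `temperature`; every simulated country must be covered
#'   from the year after its baseline through `end_year`. See
#'   [generate_scenario_inputs()].
#' @param elasticities An [elasticity_set()] (or `wash_fit`) supplying
#'   every recursion coefficient; `gamma_temp` may instead come from
#'   `gamma_temp` below.
#' @param end_year Final projected year (default 2050).
#' @param climate_gdp_coeff Change in annual GDP growth per degree C of
#'   warming (central estimate; default 0 disables the adjustment).
#' @param gamma_temp Optional externally sourced mortality-temperature
#'   coefficient, overriding the fitted one.
#' @param include_temperature_mortality Include the temperature term in the
#'   mortality recursion (default `TRUE`).
#' @param dy_mode `"log"` (default) drives the recursions with changes in
#'   ln GDP per capita; `"level"` uses level changes.
#' @param clip Apply range bounds after each annual step (default `TRUE`).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(paths, elasticities, end_year = 2050L,
                            climate_gdp_coeff = 0,
                            gamma_temp = NULL,
                            include_temperature_mortality = TRUE,
                            dy_mode = c("log", "level"),
                            clip = TRUE) {
  dy_mode <- match.arg(dy_mode)
  if (inherits(elasticities, "wash_fit")) {
    elasticities <- elasticities$elasticities
  }
  stopifnot(inherits(elasticities, "elasticity_set"), is.data.frame(paths))
  need <- c("country_id", "year", "gdp_pc", "population", "urban_share")
  miss <- setdiff(need, names(paths))
  if (length(miss)) {
    stop("scenario paths lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"temperature" %in% names(paths)) paths$temperature <- 0
  structure(list(paths = paths, elasticities = elasticities,
                 end_year = as.integer(end_year),
                 climate_gdp_coeff = climate_gdp_coeff,
                 gamma_temp = gamma_temp,
                 include_temperature_mortality = include_temperature_mortality,
                 dy_mode = dy_mode, clip = clip),
            class = "scenario_config")
}

#' Run the full forward simulation
#'
#' For every country in the scenario: take starting values (coverage,
#' mortality rate, collection time, GDP) from its latest observed panel
#' year; temperature-adjust the annual GDP growth implied by the exogenous
#' path; then step the coverage recursions, the mortality recursion and the
#' collection-time recursion year by year to the scenario horizon,
#' computing annual deaths as rate/1000 x population. Piped coverage is
#' additionally capped at improved coverage after each step (the
#' definitions are nested). Deterministic given its inputs.
#'
#' @param scenario A [scenario_config()].
#' @param baseline A [wash_panel] supplying each country's starting values
#'   at its latest observed year.
#' @return A `wash_projection`: data frame with one row per (country,
#'   year) — baseline year included with `observed = TRUE` — and columns
#'   `gdp_pc`, `population`, `urban_share`, `coverage_improved`,
#'   `coverage_piped`, `mortality_wash`, `deaths`, `collection_time`,
#'   `clipped` (count of bound events at that country-year). Attribute
#'   `"n_clipped"` totals bound events.
#' @export
run_projection <- function(scenario, baseline) {
  stopifnot(inherits(scenario, "scenario_config"),
            inherits(baseline, "wash_panel"))
  es <- scenario$elasticities
  base <- panel_baseline(baseline)
  paths <- scenario$paths
  countries <- sort(unique(paths$country_id))
  missing_countries <- setdiff(countries, base$country_id)
  if (length(missing_countries)) {
    stop("scenario country not in baseline panel: ",
         paste(missing_countries, collapse = ", "), call. = FALSE)
  }
  g_temp <- scenario$gamma_temp %||% ela(es, "gamma_temp", default = 0)
  if (!scenario$include_temperature_mortality) g_temp <- 0
  out <- vector("list", length(countries))
  for (k in seq_along(countries)) {
    cid <- countries[k]
    b <- base[base$country_id == cid, ]
    p <- paths[paths$country_id == cid & paths$year > b$year &
                 paths$year <= scenario$end_year, , drop = FALSE]
    p <- p[order(p$year), ]
    if (!nrow(p) || !identical(p$year, seq(b$year + 1L, scenario$end_year))) {
      stop("scenario paths for ", cid, " do not cover every year from ",
           b$year + 1L, " to ", scenario$end_year, call. = FALSE)
    }
    gdp_path <- c(b$gdp_pc, p$gdp_pc)
    temp_path <- c(b$temperature %||% 0, p$temperature)
    if (is.na(temp_path[1])) temp_path[1] <- p$temperature[1]
    dT <- diff(temp_path)
    growth <- diff(log(gdp_path))
    growth <- adjust_gdp_growth(growth, dT, scenario$climate_gdp_coeff)
    gdp_adj <- b$gdp_pc * exp(cumsum(growth))
    dlnY <- if (scenario$dy_mode == "log") growth else
      diff(c(b$gdp_pc, gdp_adj))
    urb_path <- c(b$urban_share, p$urban_share)
    dUrban <- diff(urb_path)
    cov_imp <- project_coverage(b$coverage_improved, dlnY, dUrban,
                                ela(es, "kappa_Y_improved"),
                                ela(es, "kappa_urban_improved"),
                                clip = scenario$clip)
    cov_pip <- project_coverage(b$coverage_piped, dlnY, dUrban,
                                ela(es, "kappa_Y_piped"),
                                ela(es, "kappa_urban_piped"),
                                clip = scenario$clip)
    capped <- scenario$clip & cov_pip > cov_imp
    cov_pip_c <- ifelse(capped, cov_imp, cov_pip)
    d_imp <- diff(c(b$coverage_improved, cov_imp))
    d_pip <- diff(c(b$coverage_piped, cov_pip_c))
    mort <- project_mortality(b$mortality_wash, dlnY, d_imp, d_pip, dT,
                              ela(es, "alpha_Y"), ela(es, "beta_imp"),
                              ela(es, "beta_piped"), g_temp,
                              floor = scenario$clip)
    ct <- project_collection_time(b$collection_time, dlnY, dUrban,
                                  ela(es, "theta_Y"),
                                  ela(es, "gamma_urban"),
                                  floor = scenario$clip)
    n_clip <- attr(cov_imp, "n_clipped") + attr(cov_pip, "n_clipped") +
      sum(capped) + attr(mort, "n_clipped") + attr(ct, "n_clipped")
    df <- data.frame(
      country_id = cid,
      year = c(b$year, p$year),
      observed = c(TRUE, rep(FALSE, nrow(p))),
      gdp_pc = c(b$gdp_pc, gdp_adj),
      population = c(b$population, p$population),
      urban_share = urb_path,
      temperature = temp_path,
      coverage_improved = c(b$coverage_improved, as.numeric(cov_imp)),
      coverage_piped = c(b$coverage_piped, as.numeric(cov_pip_c)),
      mortality_wash = c(b$mortality_wash, as.numeric(mort)),
      collection_time = c(b$collection_time, as.numeric(ct)),
      stringsAsFactors = FALSE
    )
    df$deaths <- compute_deaths(df$mortality_wash, df$population)
    attr(df, "n_clipped") <- n_clip
    out[[k]] <- df
  }
  total_clipped <- sum(vapply(out, attr, numeric(1), "n_clipped"))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, n_clipped = total_clipped,
            class = c("wash_projection", "data.frame"))
}

#' @export
print.wash_projection <- function(x, ...) {
  cat(sprintf(
    "<wash_projection> %d countries, years %d-%d, %d bound event(s)\n",
    length(unique(x$country_id)), min(x$year), max(x$year),
    attr(x, "n_clipped")))
  invisible(x)
}

#' @export
plot.wash_projection <- function(x, field = "mortality_wash", ...) {
  yrs <- sort(unique(x$year))
  ids <- unique(x$country_id)
  m <- sapply(ids, function(cid) {
    d <- x[x$country_id == cid, ]
    d[[field]][match(yrs, d$year)]
  })
  graphics::matplot(yrs, m, type = "l", lty = 1,
                    col = grDevices::hcl.colors(max(2L, length(ids)),
                                                "Dark 3"),
                    xlab = "year", ylab = field, ...)
  obs_max <- suppressWarnings(max(x$year[x$observed]))
  if (is.finite(obs_max)) graphics::abline(v = obs_max, lty = 3)
  invisible(x)
}
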