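# Economic losses: mortality and morbidity valued through a VSL benefit
# transfer, collection time valued at an opportunity cost tied to the
# income of the bottom 80 percent. All flows are annual, in the scenario's
# constant currency (the panel's GDP unit); no discounting across years.

#' Configure the economic valuation
#'
#' `vsl_ref` and `y_ref` anchor the VSL benefit transfer and carry the
#' currency level; they have no defaults because the transfer anchor is an
#' analyst's choice, not a property of the simulation. The remaining
#' defaults: morbidity losses are 25% of mortality losses (sensitivity
#' range 0.10-0.40); households make 2 one-way collection trips per day,
#' 365 days per year; the opportunity cost of time is 50% of bottom-80%
#' per-capita income spread over 2,000 working hours per year
#' (`time_value_fraction` and `work_hours_per_year` are implementation
#' defaults, not sourced values — set them from your own valuation study).
#'
#' @param vsl_ref VSL (currency) at the reference income `y_ref`.
#' @param y_ref Reference GDP per capita (currency/year).
#' @param vsl_income_elasticity Income elasticity of the VSL (>= 0,
#'   default 1).
#' @param f_morb Morbidity fraction in \[0, 1) (default 0.25).
#' @param time_value_fraction Fraction of bottom-80% per-capita GDP valuing
#'   an hour of collection time, in (0, 1\] (default 0.5).
#' @param trips_per_day One-way trips per household per day (default 2,
#'   i.e. one round trip).
#' @param days_per_year Collection days per year (default 365).
#' @param work_hours_per_year Hours converting annual income to an hourly
#'   rate (default 2000).
#' @return An object of class `valuation_config`.
#' @export
valuation_config <- function(vsl_ref, y_ref, vsl_income_elasticity = 1,
                             f_morb = 0.25, time_value_fraction = 0.5,
                             trips_per_day = 2, days_per_year = 365L,
                             work_hours_per_year = 2000) {
  stopifnot(vsl_ref > 0, y_ref > 0, vsl_income_elasticity >= 0,
            f_morb >= 0, f_morb < 1,
            time_value_fraction > 0, time_value_fraction <= 1,
            trips_per_day > 0, days_per_year > 0, work_hours_per_year > 0)
  structure(list(vsl_ref = vsl_ref, y_ref = y_ref,
                 vsl_income_elasticity = vsl_income_elasticity,
                 f_morb = f_morb, time_value_fraction = time_value_fraction,
                 trips_per_day = trips_per_day,
                 days_per_year = as.integer(days_per_year),
                 work_hours_per_year = work_hours_per_year),
            class = "valuation_config")
}

#' Forecast the value of statistical life
#'
#' Power-law benefit transfer:
#' `VSL = vsl_ref * (gdp_pc / y_ref)^elasticity`, so the VSL rises with
#' GDP per capita along any growth path.
#'
#' @param gdp_pc GDP per capita (currency/year), positive.
#' @param config A [valuation_config()].
#' @return VSL in the config's currency.
#' @export
forecast_vsl <- function(gdp_pc, config) {
  stopifnot(inherits(config, "valuation_config"))
  if (any(gdp_pc <= 0, na.rm = TRUE)) {
    stop("gdp_pc must be positive for the VSL transfer", call. = FALSE)
  }
  config$vsl_ref * (gdp_pc / config$y_ref)^config$vsl_income_elasticity
}

#' Opportunity cost of collection time
#'
#' Hourly value of time as a fraction of the average per-capita income of
#' the bottom 80 percent of the income distribution:
#' `v = fraction * (share_b80 * gdp_pc / 0.8) / work_hours_per_year`
#' (the bottom 80% hold `share_b80` of GDP and 80% of the population).
#'
#' @param gdp_pc GDP per capita (currency/year), positive.
#' @param income_share_b80 Fraction of GDP held by the bottom 80%.
#' @param config A [valuation_config()].
#' @return Currency per hour.
#' @export
opportunity_cost_of_time <- function(gdp_pc, income_share_b80, config) {
  stopifnot(inherits(config, "valuation_config"),
            all(gdp_pc > 0, na.rm = TRUE),
            all(income_share_b80 > 0, na.rm = TRUE))
  config$time_value_fraction * (income_share_b80 * gdp_pc / 0.8) /
    config$work_hours_per_year
}

#' Health-related losses
#'
#' Mortality losses are projected deaths times the VSL; morbidity losses
#' are a fixed fraction of mortality losses:
#' `H = population * rate/1000 * VSL * (1 + f_morb)`.
#'
#' @param population Persons.
#' @param rate WASH mortality rate (deaths/1,000/year).
#' @param vsl Value of statistical life (currency).
#' @param f_morb Morbidity fraction in \[0, 1).
#' @return Data frame with `mortality_component`, `morbidity_component`
#'   (`= f_morb * mortality_component`), and their sum `health_loss`
#'   (currency/year).
#' @export
health_losses <- function(population, rate, vsl, f_morb = 0.25) {
  stopifnot(all(population >= 0, na.rm = TRUE), all(rate >= 0, na.rm = TRUE),
            all(vsl >= 0, na.rm = TRUE), f_morb >= 0, f_morb < 1)
  mortality <- population * rate / 1000 * vsl
  morbidity <- f_morb * mortality
  data.frame(mortality_component = mortality,
             morbidity_component = morbidity,
             health_loss = mortality + morbidity)
}

#' Time-collection losses
#'
#' Households (population / household size) make `trips_per_day` one-way
#' trips of `collection_time` minutes, valued at `v` per hour over
#' `days_per_year` days:
#' `T = population/hhsize * trips * time/60 * v * days`.
#'
#' @param population Persons.
#' @param household_size Persons per household, positive.
#' @param collection_time One-way collection time (minutes).
#' @param v Opportunity cost of time (currency/hour).
#' @param config A [valuation_config()].
#' @return Time losses (currency/year).
#' @export
time_losses <- function(population, household_size, collection_time, v,
                        config) {
  stopifnot(inherits(config, "valuation_config"),
            all(population >= 0, na.rm = TRUE),
            all(collection_time >= 0, na.rm = TRUE),
            all(v >= 0, na.rm = TRUE))
  if (any(household_size <= 0, na.rm = TRUE)) {
    stop("household_size must be positive", call. = FALSE)
  }
  (population / household_size) * config$trips_per_day *
    (collection_time / 60) * v * config$days_per_year
}

#' Total losses
#'
#' `total = H + T`: health- plus time-related losses.
#'
#' @param H Health losses (currency/year), nonnegative.
#' @param T_ Time losses (currency/year), nonnegative.
#' @return Total losses.
#' @export
total_losses <- function(H, T_) {
  stopifnot(all(H >= 0, na.rm = TRUE), all(T_ >= 0, na.rm = TRUE))
  H + T_
}

#' Build the loss ledger for a projection
#'
#' Applies the VSL transfer, the opportunity cost of time, and the health-
#' and time-loss formulas at every (country, year) of a projection.
#' `income_share_b80` and `household_size` are taken from each country's
#' latest observed panel year and held constant over the horizon.
#'
#' @param projection A `wash_projection` from [run_projection()].
#' @param baseline The [wash_panel] used for the projection (source of
#'   income shares and household sizes).
#' @param valuation A [valuation_config()].
#' @return A `loss_ledger` data frame: one row per (country, year) with
#'   `vsl`, `value_of_time`, `mortality_component`, `morbidity_component`,
#'   `health_loss`, `time_loss`, `total_loss`, and per-capita variants
#'   (`health_loss_pc`, `time_loss_pc`, `total_loss_pc`).
#' @export
compute_losses <- function(projection, baseline, valuation) {
  stopifnot(inherits(projection, "wash_projection"),
            inherits(baseline, "wash_panel"),
            inherits(valuation, "valuation_config"))
  base <- panel_baseline(baseline)
  idx <- match(projection$country_id, base$country_id)
  if (anyNA(idx)) {
    stop("projection country missing from baseline panel: ",
         paste(unique(projection$country_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  share <- base$income_share_b80[idx]
  hhsize <- base$household_size[idx]
  if (anyNA(share) || anyNA(hhsize)) {
    stop("baseline panel lacks income_share_b80 or household_size for some countries",
         call. = FALSE)
  }
  out <- data.frame(country_id = projection$country_id,
                    year = projection$year,
                    stringsAsFactors = FALSE)
  out$vsl <- forecast_vsl(projection$gdp_pc, valuation)
  out$value_of_time <- opportunity_cost_of_time(projection$gdp_pc, share,
                                                valuation)
  hl <- health_losses(projection$population, projection$mortality_wash,
                      out$vsl, valuation$f_morb)
  out$mortality_component <- hl$mortality_component
  out$morbidity_component <- hl$morbidity_component
  out$health_loss <- hl$health_loss
  out$time_loss <- time_losses(projection$population, hhsize,
                               projection$collection_time,
                               out$value_of_time, valuation)
  out$total_loss <- total_losses(out$health_loss, out$time_loss)
  out$health_loss_pc <- out$health_loss / projection$population
  out$time_loss_pc <- out$time_loss / projection$population
  out$total_loss_pc <- out$total_loss / projection$population
  structure(out, class = c("loss_ledger", "data.frame"))
}

#' @export
print.loss_ledger <- function(x, ...) {
  cat(sprintf("<loss_ledger> %d rows; total losses %.4g (currency/yr) at horizon\n",
              nrow(x), sum(x$total_loss[x$year == max(x$year)])))
  invisible(x)
}
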