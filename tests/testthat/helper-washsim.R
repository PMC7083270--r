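# Shared fixture builders. Everything is generated in code at test time.

# Agreement to `digits` significant digits, with the tolerance anchored to
# the magnitude of the quantities compared (so series that pass through
# zero are judged on the scale of the computation, not of the crossing).
expect_sig_digits <- function(actual, expected, digits) {
  scale <- max(abs(actual), abs(expected), 1e-300)
  tol <- scale * 10^-digits
  expect_true(all(abs(actual - expected) <= tol),
              label = sprintf("max err %.3g vs %d significant digits at scale %.3g",
                              max(abs(actual - expected)), digits, scale))
}

# Small noise-free generator config: outcomes are exact structural indices.
exact_cfg <- function(n_countries = 8, years = 1995:2010, seed = 42, ...) {
  synth_config(n_countries = n_countries, years = years,
               noise_sd = list(coverage = 0, mortality = 0, time = 0),
               seed = seed, ...)
}

# Tiny hand-built panel data frame (2 countries x 3 years).
tiny_panel_df <- function() {
  data.frame(
    country_id = rep(c("AAA", "BBB"), each = 3),
    year = rep(2000:2002, 2),
    gdp_pc = c(1000, 1050, 1100, 2000, 2100, 2200),
    population = c(1e6, 1.02e6, 1.04e6, 5e6, 5.1e6, 5.2e6),
    urban_share = c(0.30, 0.31, 0.32, 0.50, 0.51, 0.52),
    coverage_improved = c(0.50, 0.52, 0.54, 0.70, 0.71, 0.72),
    coverage_piped = c(0.20, 0.21, 0.22, 0.40, 0.41, 0.42),
    mortality_wash = c(2.0, 1.9, 1.8, 1.0, 0.95, 0.9),
    collection_time = c(30, 29, 28, 15, 14.5, 14),
    temperature = c(0, 0.02, 0.04, 0, 0.02, 0.04),
    income_share_b80 = rep(0.4, 6),
    household_size = rep(5, 6),
    ctrl_fertility = rep(c(5.1, 3.2), each = 3),
    stringsAsFactors = FALSE
  )
}

quiet_fit <- function(...) suppressMessages(wash_fit(...))

# Base valuation used across loss/pipeline tests.
test_valuation <- function(...) {
  valuation_config(vsl_ref = 1e5, y_ref = 2000, ...)
}
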