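test_that("recursions match the cumulative-sum closed form", {
  # constant drivers: value after k steps = start + k * per-step change
  cov <- project_coverage(0.40, rep(0.1, 3), rep(0.01, 3),
                          kappa_Y = 0.05, kappa_urban = 0.2)
  expect_sig_digits(cov[3], 0.421, 12)
  expect_sig_digits(as.numeric(cov), 0.40 + (1:3) * 0.007, 12)

  mort <- project_mortality(2.0, rep(0.1, 10), rep(0.01, 10),
                            rep(0.005, 10), rep(0.02, 10),
                            alpha_Y = -0.5, beta_imp = -2.0,
                            beta_piped = -3.0, gamma_temp = 0.05)
  expect_sig_digits(as.numeric(mort), 2.0 - (1:10) * 0.084, 12)
  expect_sig_digits(mort[10], 1.16, 12)

  ct <- project_collection_time(30, rep(0.05, 10), rep(0.005, 10),
                                theta_Y = -1.0, gamma_urban = -10)
  expect_sig_digits(ct[10], 29.0, 12)

  expect_equal(adjust_gdp_growth(0.030, 0.5, -0.005), 0.0275)
  expect_equal(adjust_gdp_growth(0.030, 0, -0.005), 0.030)
  expect_equal(adjust_gdp_growth(0.030, 0.5, 0), 0.030)

  expect_equal(compute_deaths(1.5, 2e6), 3000)
  expect_equal(compute_deaths(0, 2e6), 0)
  expect_equal(compute_deaths(1.5, 0), 0)
})

test_that("bounds clip, stay clipped, and are counted", {
  cov <- project_coverage(0.9, rep(0.5, 5), rep(0, 5), 1, 0)
  expect_equal(as.numeric(cov), rep(1, 5))
  expect_equal(attr(cov, "n_clipped"), 5L)
  mort <- project_mortality(0.5, rep(1, 4), rep(0, 4), rep(0, 4), rep(0, 4),
                            alpha_Y = -2, beta_imp = 0, beta_piped = 0)
  expect_equal(as.numeric(mort), rep(0, 4))
  ct <- project_collection_time(5, rep(1, 4), rep(0, 4), -10, 0)
  expect_equal(as.numeric(ct), rep(0, 4))
  # pre-clipping closed form is available behind the toggles
  raw <- project_coverage(0.9, rep(0.5, 5), rep(0, 5), 1, 0, clip = FALSE)
  expect_sig_digits(as.numeric(raw), 0.9 + (1:5) * 0.5, 12)
})

test_that("zero elasticities hold every outcome at its baseline", {
  cfg <- exact_cfg(n_countries = 3, years = 2000:2005, seed = 2)
  p <- generate_panel(cfg)
  es0 <- elasticity_set(kappa_Y_improved = 0, kappa_urban_improved = 0,
                        kappa_Y_piped = 0, kappa_urban_piped = 0,
                        alpha_Y = 0, beta_imp = 0, beta_piped = 0,
                        gamma_temp = 0, theta_Y = 0, gamma_urban = 0)
  sc <- scenario_config(generate_scenario_inputs(cfg, 2006:2015), es0,
                        end_year = 2015)
  proj <- run_projection(sc, p)
  base <- p[p$year == 2005, ]
  for (cid in base$country_id) {
    d <- proj[proj$country_id == cid, ]
    b <- base[base$country_id == cid, ]
    expect_equal(d$mortality_wash, rep(b$mortality_wash, nrow(d)))
    expect_equal(d$coverage_improved, rep(b$coverage_improved, nrow(d)))
    expect_equal(d$collection_time, rep(b$collection_time, nrow(d)))
  }
})

test_that("a single-country run composes the per-step operations", {
  cfg <- exact_cfg(n_countries = 1, years = 2000:2005, seed = 17)
  p <- generate_panel(cfg)
  paths <- generate_scenario_inputs(cfg, 2006:2020)
  es <- cfg$true_elasticities
  sc <- scenario_config(paths, es, end_year = 2020)
  proj <- run_projection(sc, p)
  b <- p[p$year == 2005, ]
  dlnY <- diff(log(c(b$gdp_pc, paths$gdp_pc)))
  dUrb <- diff(c(b$urban_share, paths$urban_share))
  dT <- diff(c(b$temperature, paths$temperature))
  tr <- coef(es)
  imp <- project_coverage(b$coverage_improved, dlnY, dUrb,
                          tr["kappa_Y_improved"], tr["kappa_urban_improved"])
  pip <- project_coverage(b$coverage_piped, dlnY, dUrb,
                          tr["kappa_Y_piped"], tr["kappa_urban_piped"])
  mort <- project_mortality(b$mortality_wash, dlnY,
                            diff(c(b$coverage_improved, imp)),
                            diff(c(b$coverage_piped, pip)), dT,
                            tr["alpha_Y"], tr["beta_imp"], tr["beta_piped"],
                            tr["gamma_temp"])
  fc <- proj[!proj$observed, ]
  expect_sig_digits(fc$coverage_improved, as.numeric(imp), 12)
  expect_sig_digits(fc$mortality_wash, as.numeric(mort), 12)
  expect_sig_digits(fc$deaths, as.numeric(mort) / 1000 * fc$population, 12)
})

test_that("results are invariant to input row order", {
  cfg <- exact_cfg(n_countries = 4, years = 2000:2005, seed = 9)
  p <- generate_panel(cfg)
  paths <- generate_scenario_inputs(cfg, 2006:2015)
  sc1 <- scenario_config(paths, cfg$true_elasticities, end_year = 2015)
  set.seed(1)
  paths2 <- paths[sample(nrow(paths)), ]
  sc2 <- scenario_config(paths2, cfg$true_elasticities, end_year = 2015)
  expect_equal(run_projection(sc1, p), run_projection(sc2, p))
})

test_that("faster coverage growth lowers mortality pointwise", {
  cfg <- exact_cfg(n_countries = 5, years = 2000:2005, seed = 23)
  p <- generate_panel(cfg)
  paths <- generate_scenario_inputs(cfg, 2006:2030)
  es <- cfg$true_elasticities  # beta_imp, beta_piped < 0
  boost <- es
  boost$entries$kappa_Y_improved$estimate <- 0.10
  boost$entries$kappa_Y_piped$estimate <- 0.06
  slow <- run_projection(scenario_config(paths, es, end_year = 2030,
                                         clip = FALSE), p)
  fast <- run_projection(scenario_config(paths, boost, end_year = 2030,
                                         clip = FALSE), p)
  expect_true(all(fast$coverage_improved[!fast$observed] >
                    slow$coverage_improved[!slow$observed]))
  expect_true(all(fast$mortality_wash[!fast$observed] <
                    slow$mortality_wash[!slow$observed]))
})

test_that("temperature feeds back through growth and mortality", {
  cfg <- exact_cfg(n_countries = 3, years = 2000:2005, seed = 5,
                   temp_ramp = 0.05)
  p <- generate_panel(cfg)
  paths <- generate_scenario_inputs(cfg, 2006:2030)
  es <- cfg$true_elasticities
  warm <- run_projection(scenario_config(paths, es, end_year = 2030,
                                         climate_gdp_coeff = -0.05), p)
  cool <- run_projection(scenario_config(paths, es, end_year = 2030,
                                         climate_gdp_coeff = 0), p)
  expect_true(all(warm$gdp_pc[!warm$observed] < cool$gdp_pc[!cool$observed]))
  # lower income growth means slower coverage gains, hence more mortality
  expect_true(all(warm$mortality_wash[!warm$observed] >=
                    cool$mortality_wash[!cool$observed]))
  # switching the temperature-mortality channel off changes the path
  no_t <- run_projection(scenario_config(
    paths, es, end_year = 2030, include_temperature_mortality = FALSE), p)
  expect_false(isTRUE(all.equal(no_t$mortality_wash, cool$mortality_wash)))
})

test_that("piped coverage never exceeds improved coverage after capping", {
  es <- default_true_elasticities()
  es$entries$kappa_Y_piped$estimate <- 1.0  # force piped above improved
  cfg <- exact_cfg(n_countries = 3, years = 2000:2005, seed = 44)
  p <- generate_panel(cfg)
  sc <- scenario_config(generate_scenario_inputs(cfg, 2006:2040), es,
                        end_year = 2040)
  proj <- run_projection(sc, p)
  expect_true(all(proj$coverage_piped <= proj$coverage_improved + 1e-12))
  expect_gt(attr(proj, "n_clipped"), 0)
})

test_that("missing countries and short paths are configuration errors", {
  cfg <- exact_cfg(n_countries = 3, years = 2000:2005, seed = 2)
  p <- generate_panel(cfg)
  paths <- generate_scenario_inputs(cfg, 2006:2015)
  extra <- paths[paths$country_id == "C01", ]
  extra$country_id <- "ZZZ"
  sc <- scenario_config(rbind(paths, extra), cfg$true_elasticities,
                        end_year = 2015)
  expect_error(run_projection(sc, p), "ZZZ")
  sc2 <- scenario_config(paths[paths$year <= 2010, ],
                         cfg$true_elasticities, end_year = 2015)
  expect_error(run_projection(sc2, p), "cover every year")
})
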