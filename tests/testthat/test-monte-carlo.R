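test_that("the sampler is reproducible and honours each family", {
  dists <- parameter_distributions(
    elasticities = list(beta_imp = param_dist("normal", mean = -2, sd = 0.2,
                                              min = -2.4, max = -1.6),
                        alpha_Y = param_dist("fixed", value = -0.5)),
    climate_gdp_coeff = param_dist("triangular", min = -0.01, max = 0,
                                   mode = -0.005),
    n_draws = 500, seed = 77)
  d1 <- sample_parameters(dists, countries = c("A", "B"))
  d2 <- sample_parameters(dists, countries = c("A", "B"))
  expect_identical(d1, d2)
  expect_setequal(colnames(d1),
                  c("growth_A", "growth_B", "beta_imp", "alpha_Y",
                    "climate_gdp_coeff", "f_morb"))
  expect_true(all(d1[, "alpha_Y"] == -0.5))            # fixed family
  expect_true(all(d1[, "beta_imp"] >= -2.4 & d1[, "beta_imp"] <= -1.6))
  expect_true(all(d1[, "f_morb"] >= 0.10 & d1[, "f_morb"] <= 0.40))
  expect_true(all(d1[, "climate_gdp_coeff"] >= -0.01 &
                    d1[, "climate_gdp_coeff"] <= 0))
  # growth columns are independent per country
  expect_false(identical(d1[, "growth_A"], d1[, "growth_B"]))
})

test_that("all-fixed distributions collapse every draw to the point values", {
  dists <- parameter_distributions(
    growth = param_dist("fixed", value = 0.037),
    f_morb = param_dist("fixed", value = 0.25),
    n_draws = 20, seed = 5)
  d <- sample_parameters(dists, countries = "C01")
  expect_true(all(d[, "growth_C01"] == 0.037))
  expect_true(all(d[, "f_morb"] == 0.25))
  expect_equal(nrow(unique(d)), 1L)
})

test_that("CI-derived elasticity distributions centre on the fit", {
  es <- elasticity_set(
    beta_imp = list(estimate = -2, se = 0.1, ci = c(-2.2, -1.8)),
    alpha_Y = -0.5)  # no CI: sampled as fixed
  ed <- elasticity_dists(es, params = c("beta_imp", "alpha_Y"))
  expect_equal(ed$beta_imp$family, "normal")
  expect_equal(ed$beta_imp$mean, -2)
  expect_equal(ed$beta_imp$sd, 0.4 / (2 * qnorm(0.975)), tolerance = 1e-10)
  expect_equal(ed$alpha_Y$family, "fixed")
  # default selection keeps only coefficients with an interval
  expect_identical(names(elasticity_dists(es)), "beta_imp")
})

test_that("a degenerate ensemble reproduces the base case at every quantile", {
  cfg <- exact_cfg(n_countries = 4, years = 2000:2006, seed = 13,
                   growth_mean = 0.037, growth_sd = 0)
  p <- generate_panel(cfg)
  sc <- scenario_config(generate_scenario_inputs(cfg, 2007:2025),
                        cfg$true_elasticities, end_year = 2025)
  val <- test_valuation()
  dists <- parameter_distributions(
    growth = param_dist("fixed", value = 0.037),
    f_morb = param_dist("fixed", value = val$f_morb),
    n_draws = 8, seed = 3)
  e1 <- run_ensemble(dists, sc, p, val)
  expect_length(e1$failed, 0L)
  for (o in names(e1$quantiles)) {
    q <- e1$quantiles[[o]]
    expect_equal(unname(q["q25", ]), unname(q["q75", ]), label = o)
    expect_equal(unname(q["q50", ]), e1$base[[o]], tolerance = 1e-10,
                 label = o)
  }
  e2 <- run_ensemble(dists, sc, p, val)
  expect_identical(e1, e2)  # seeded reruns are identical
})

test_that("wider growth uncertainty widens the interquartile band", {
  cfg <- exact_cfg(n_countries = 3, years = 2000:2006, seed = 21)
  p <- generate_panel(cfg)
  sc <- scenario_config(generate_scenario_inputs(cfg, 2007:2030),
                        cfg$true_elasticities, end_year = 2030)
  val <- test_valuation()
  mk <- function(sd) parameter_distributions(
    growth = param_dist("normal", mean = 0.037, sd = sd),
    f_morb = param_dist("fixed", value = 0.25),
    n_draws = 120, seed = 10)
  narrow <- run_ensemble(mk(0.005), sc, p, val)
  wide <- run_ensemble(mk(0.020), sc, p, val)
  iqr_at_end <- function(e) {
    q <- e$quantiles$mortality_rate
    q["q75", ncol(q)] - q["q25", ncol(q)]
  }
  expect_gt(iqr_at_end(wide), iqr_at_end(narrow))
})

test_that("failing draws are recorded and skipped, never silent", {
  cfg <- exact_cfg(n_countries = 2, years = 2000:2005, seed = 4)
  p <- generate_panel(cfg)
  sc <- scenario_config(generate_scenario_inputs(cfg, 2006:2015),
                        cfg$true_elasticities, end_year = 2015)
  dists <- parameter_distributions(
    growth = param_dist("fixed", value = 0.037),
    elasticities = list(alpha_Y = param_dist("fixed", value = NaN)),
    n_draws = 3, seed = 2)
  expect_warning(e <- run_ensemble(dists, sc, p, test_valuation()),
                 "3 of 3 draws failed")
  expect_length(e$failed, 3L)
  expect_true(all(is.na(e$outputs$mortality_rate)))
})

test_that("variance decomposition recovers analytic shares", {
  set.seed(2024)
  n <- 10000
  draws <- cbind(a = rnorm(n), b = rnorm(n))
  vd <- variance_decomposition(draws, 2 * draws[, "a"] + draws[, "b"])
  expect_equal(unname(vd$shares["a"]), 0.8, tolerance = 0.02)
  expect_equal(unname(vd$shares["b"]), 0.2, tolerance = 0.02)
  expect_lt(vd$residual, 1e-10)  # exactly linear model

  # single driver: full share to it, none elsewhere
  vd1 <- variance_decomposition(draws, 3 * draws[, "b"])
  expect_equal(unname(vd1$shares["b"]), 1, tolerance = 1e-10)
  expect_equal(unname(vd1$shares["a"]), 0, tolerance = 1e-3)

  # independent output: all shares near zero
  vd0 <- variance_decomposition(draws, rnorm(n))
  expect_true(all(vd0$shares < 0.01))
  expect_gt(vd0$residual, 0.95)

  # collinear parameters are named in the error
  bad <- cbind(draws, c = draws[, "a"] + draws[, "b"])
  expect_error(variance_decomposition(bad, 2 * bad[, "a"] + bad[, "b"]),
               "collinear")

  # fixed (constant) parameter columns are excluded, not crashed on
  fx <- cbind(draws, k = 1)
  vdf <- variance_decomposition(fx, 2 * fx[, "a"] + fx[, "b"])
  expect_equal(unname(vdf$shares["k"]), 0)
  # linear-decomposition bound, up to finite-sample parameter correlation
  expect_equal(sum(vdf$shares), 1, tolerance = 0.05)
})
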