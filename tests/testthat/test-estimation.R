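test_that("noise-free panels return the generator's elasticities", {
  cfg <- exact_cfg(n_countries = 25, years = 1991:2010, seed = 12)
  p <- generate_panel(cfg)
  fit <- quiet_fit(p)
  truth <- coef(cfg$true_elasticities)
  est <- coef(fit)
  for (nm in names(truth)) {
    expect_sig_digits(est[[nm]], truth[[nm]], 6)
  }
})

test_that("pooled fits solve the normal equations", {
  # independent brute-force least squares on the same design matrix
  cfg <- exact_cfg(n_countries = 10, years = 2000:2009, seed = 21)
  p <- generate_panel(cfg)
  out <- fit_collection_model(p)
  d <- as.data.frame(p)
  X <- cbind(1, log(d$gdp_pc), d$urban_share)
  beta <- solve(crossprod(X), crossprod(X, d$collection_time))
  expect_sig_digits(coef(out$elasticities)[["theta0"]], beta[1], 10)
  expect_sig_digits(coef(out$elasticities)[["theta_Y"]], beta[2], 10)
  expect_sig_digits(coef(out$elasticities)[["gamma_urban"]], beta[3], 10)
})

test_that("constant outcomes give near-zero slopes", {
  df <- tiny_panel_df()
  set.seed(31)
  df <- do.call(rbind, lapply(1:10, function(i) {
    d <- df
    d$country_id <- paste0(d$country_id, i)
    d$gdp_pc <- d$gdp_pc * exp(rnorm(6, 0, 0.2))
    d$urban_share <- pmin(1, d$urban_share + runif(6, -0.1, 0.3))
    d
  }))
  df$coverage_improved <- 0.5
  df$coverage_piped <- 0.2
  cov_fit <- suppressMessages(fit_coverage_model(wash_panel(df), "improved"))
  est <- cov_fit$elasticities$entries
  expect_lt(abs(est$kappa_Y_improved$estimate),
            2 * est$kappa_Y_improved$se + 1e-10)
  expect_lt(abs(est$kappa_urban_improved$estimate),
            2 * est$kappa_urban_improved$se + 1e-10)
  # an identically-zero outcome yields an all-zero fit
  g <- as.data.frame(generate_panel(synth_config(n_countries = 6,
                                                 years = 2000:2007,
                                                 seed = 47)))
  g$mortality_wash <- 0
  mort_fit <- fit_mortality_model(wash_panel(g))
  expect_true(all(abs(coef(mort_fit$elasticities)) < 1e-10))
})

test_that("shifting collection times only moves the intercept", {
  cfg <- synth_config(n_countries = 8, years = 2000:2009, seed = 14)
  p <- generate_panel(cfg)
  f1 <- fit_collection_model(p)
  d <- as.data.frame(p)
  d$collection_time <- d$collection_time + 7
  f2 <- fit_collection_model(wash_panel(d))
  e1 <- coef(f1$elasticities); e2 <- coef(f2$elasticities)
  expect_equal(e2[["theta0"]], e1[["theta0"]] + 7, tolerance = 1e-8)
  expect_equal(e2[["theta_Y"]], e1[["theta_Y"]], tolerance = 1e-8)
  expect_equal(e2[["gamma_urban"]], e1[["gamma_urban"]], tolerance = 1e-8)
})

test_that("temperature-free panels flag gamma_temp as external", {
  df <- tiny_panel_df()
  df$temperature <- NA_real_
  fit <- suppressMessages(fit_mortality_model(wash_panel(df)))
  expect_false("gamma_temp" %in% names(fit$elasticities$entries))
  expect_identical(fit$external, "gamma_temp")
  fit2 <- suppressMessages(fit_mortality_model(wash_panel(tiny_panel_df())))
  expect_true("gamma_temp" %in% names(fit2$elasticities$entries))
  expect_length(fit2$external, 0L)
})

test_that("collinear coverage columns trigger a condition-number warning", {
  df <- tiny_panel_df()
  df$coverage_piped <- df$coverage_improved
  expect_warning(fit_mortality_model(wash_panel(df)), "collinear")
})

test_that("controls are absorbed and reported", {
  cfg <- synth_config(n_countries = 10, years = 2000:2009, seed = 6)
  p <- generate_panel(cfg)
  out <- fit_collection_model(p, controls = c("ctrl_fertility",
                                              "ctrl_literacy"))
  expect_setequal(names(out$elasticities$controls),
                  c("ctrl_fertility", "ctrl_literacy"))
  expect_true(out$report$n_obs >= 5)
})

test_that("the random-effects estimator agrees on noise-free data", {
  skip_if_not_installed("lme4")
  cfg <- exact_cfg(n_countries = 10, years = 2000:2009, seed = 33)
  p <- generate_panel(cfg)
  f_re <- suppressWarnings(fit_collection_model(p, estimator = "re"))
  truth <- coef(cfg$true_elasticities)
  expect_equal(coef(f_re$elasticities)[["theta_Y"]], truth[["theta_Y"]],
               tolerance = 1e-4)
})

test_that("lag construction failures raise estimation errors", {
  df <- tiny_panel_df()[c(1, 4), ]  # one year per country
  expect_error(fit_coverage_model(wash_panel(df)), "2 periods")
  df2 <- tiny_panel_df()
  df2$collection_time <- NA_real_
  expect_error(fit_collection_model(wash_panel(df2)), "collection times")
})
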