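test_that("the narrative trajectory archetypes land in their groups", {
  th <- group_thresholds()
  # high baseline, still high at the horizon
  expect_identical(classify_country(2.0, 1.5, th), 1L)
  # moderate baseline, declining but not to negligible
  expect_identical(classify_country(1.2, 0.5, th), 2L)
  # moderate-low baseline, reaching negligible levels
  expect_identical(classify_country(0.7, 0.05, th), 3L)
  # low baseline throughout
  expect_identical(classify_country(0.4, 0.05, th), 4L)
  # boundary behaviour: baseline at the moderate threshold with a
  # non-negligible terminal rate below terminal_high falls to group 2
  expect_identical(classify_country(1.0, 0.99, th), 2L)
  expect_identical(classify_country(1.0, 1.0, th), 1L)
})

test_that("classification is a total partition for any valid thresholds", {
  set.seed(404)
  for (i in 1:200) {
    neg <- runif(1, 0.01, 0.3)
    low <- neg + runif(1, 0.01, 0.5)
    mod <- low + runif(1, 0.01, 0.5)
    th <- group_thresholds(low_baseline = low, moderate_baseline = mod,
                           negligible = neg,
                           terminal_high = neg + runif(1, 0.01, 1.5))
    g <- classify_country(runif(5, 0, 4), runif(5, 0, 4), th)
    expect_true(all(g %in% 1:4))
    expect_length(g, 5L)
  }
  expect_error(group_thresholds(low_baseline = 1, moderate_baseline = 0.5),
               "low_baseline")
})

test_that("classify_panel reads baseline and terminal rates off the run", {
  cfg <- exact_cfg(n_countries = 5, years = 2000:2008, seed = 31)
  p <- generate_panel(cfg)
  sc <- scenario_config(generate_scenario_inputs(cfg),
                        cfg$true_elasticities, end_year = 2050)
  proj <- run_projection(sc, p)
  asg <- classify_panel(proj)
  expect_setequal(asg$country_id, unique(p$country_id))
  b <- p[p$year == 2008, ]
  expect_equal(asg$baseline_rate[match(b$country_id, asg$country_id)],
               b$mortality_wash)
  term <- proj[proj$year == 2050, ]
  expect_equal(asg$terminal_rate[match(term$country_id, asg$country_id)],
               term$mortality_wash)
  expect_identical(asg$group,
                   classify_country(asg$baseline_rate, asg$terminal_rate,
                                    group_thresholds()))
  short <- run_projection(scenario_config(
    generate_scenario_inputs(cfg, 2009:2020), cfg$true_elasticities,
    end_year = 2020), p)
  expect_error(classify_panel(short), "terminal year")
})

test_that("the bundled reference grouping loads and spans all four groups", {
  path <- system.file("extdata", "ssa_groups_reference.csv",
                      package = "washsim")
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_setequal(unique(ref$group), 1:4)
  # Zimbabwe is deliberately listed twice, with the conflict annotated
  zw <- ref[ref$country == "Zimbabwe", ]
  expect_equal(nrow(zw), 2L)
  expect_true(all(nzchar(zw$note)))
  expect_equal(anyDuplicated(ref[ref$country != "Zimbabwe", "country"]), 0L)
})

test_that("group aggregation weights by population and conserves totals", {
  res <- data.frame(
    country_id = c("A", "B", "C", "D"),
    year = 2050L,
    population = c(1e6, 1e6, 1e6, 3e6),
    mortality_wash = c(1.0, 2.0, 2.0, 1.0),
    deaths = c(1000, 2000, 2000, 3000))
  asg <- data.frame(country_id = c("A", "B", "C", "D"),
                    group = c(1L, 1L, 2L, 2L))
  wm <- group_aggregate(res, asg, "mortality_wash", "weighted_mean")
  expect_equal(wm$value[wm$group == 1], 1.5)           # equal weights
  expect_equal(wm$value[wm$group == 2], (2 + 3) / 4)   # 1M vs 3M weights
  tot <- group_aggregate(res, asg, "deaths", "total")
  expect_equal(sum(tot$value), sum(res$deaths))        # conservation
  # single-country group equals the country itself
  solo <- group_aggregate(res[res$country_id == "A", ],
                          asg[asg$country_id == "A", ],
                          "mortality_wash")
  expect_equal(solo$value, 1.0)
  expect_error(group_aggregate(res, asg[-1, ], "deaths", "total"), "A")
})

test_that("summing country deaths reproduces the weighted group rate", {
  cfg <- exact_cfg(n_countries = 6, years = 2000:2006, seed = 8)
  p <- generate_panel(cfg)
  proj <- run_projection(scenario_config(
    generate_scenario_inputs(cfg, 2007:2030), cfg$true_elasticities,
    end_year = 2030), p)
  asg <- data.frame(country_id = unique(proj$country_id), group = 1L)
  rate <- group_aggregate(proj, asg, "mortality_wash", "weighted_mean")
  deaths <- group_aggregate(proj, asg, "deaths", "total")
  pop <- group_aggregate(proj, asg, "population", "total")
  expect_equal(rate$value, deaths$value / pop$value * 1000,
               tolerance = 1e-12)
  # and the weighted mean stays inside the member range
  rng <- range(proj$mortality_wash[proj$year == 2030])
  v <- rate$value[rate$year == 2030]
  expect_true(v >= rng[1] && v <= rng[2])
})
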