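# End-to-end wiring: fit -> project -> losses -> classify -> aggregate ->
# (optional) Monte Carlo, with CSV/JSON artifacts and a run manifest.

#' Run the full simulation pipeline
#'
#' Fits the elasticities from the panel (unless a fitted set is supplied),
#' projects every country to the horizon, builds the loss ledger, assigns
#' trajectory groups, aggregates per group, and optionally runs the Monte
#' Carlo ensemble. When `out_dir` is given, writes `elasticities.json`,
#' `projections.csv`, `losses.csv`, `groups.csv`,
#' `group_<field>.csv` aggregates, per-output ensemble quantile CSVs, and a
#' `manifest.json` recording inputs, seed and package version. All
#' randomness derives from the single `seed`, fanned out to named
#' substreams.
#'
#' @param panel A [wash_panel] of observed country-years.
#' @param paths Exogenous projection paths (see [scenario_config()]).
#' @param valuation A [valuation_config()].
#' @param thresholds A [group_thresholds()]; by default the terminal year
#'   follows `end_year`.
#' @param elasticities Optional pre-fitted [elasticity_set()]; default fits
#'   [wash_fit()] on `panel`.
#' @param dists Optional [parameter_distributions()] switching on the
#'   Monte Carlo stage.
#' @param end_year Projection horizon (default 2050).
#' @param climate_gdp_coeff Growth adjustment per degree C (default 0).
#' @param gamma_temp Optional external mortality-temperature coefficient.
#' @param out_dir Optional artifact directory (created if missing).
#' @param seed Top-level integer seed (default 1).
#' @return A `wash_pipeline` list: `fit`, `scenario`, `projection`,
#'   `losses`, `groups`, `aggregates` (named list of per-group series),
#'   `ensemble` (or `NULL`), `manifest`.
#' @export
run_pipeline <- function(panel, paths, valuation,
                         thresholds = NULL,
                         elasticities = NULL, dists = NULL,
                         end_year = 2050L, climate_gdp_coeff = 0,
                         gamma_temp = NULL, out_dir = NULL, seed = 1L) {
  stopifnot(inherits(panel, "wash_panel"),
            inherits(valuation, "valuation_config"))
  if (is.null(thresholds)) {
    thresholds <- group_thresholds(terminal_year = end_year)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  fit <- if (is.null(elasticities)) stage("estimate", wash_fit(panel))
         else elasticities
  es <- if (inherits(fit, "wash_fit")) fit$elasticities else fit
  scenario <- stage("scenario", scenario_config(
    paths, es, end_year = end_year, climate_gdp_coeff = climate_gdp_coeff,
    gamma_temp = gamma_temp))
  projection <- stage("project", run_projection(scenario, panel))
  ledger <- stage("losses", compute_losses(projection, panel, valuation))
  groups <- stage("classify", classify_panel(projection, thresholds))
  merged <- cbind(as.data.frame(projection),
                  ledger[setdiff(names(ledger), c("country_id", "year"))])
  aggregates <- stage("aggregate", list(
    mortality_rate = group_aggregate(merged, groups, "mortality_wash",
                                     "weighted_mean"),
    deaths = group_aggregate(merged, groups, "deaths", "total"),
    collection_time = group_aggregate(merged, groups, "collection_time",
                                      "weighted_mean"),
    health_loss = group_aggregate(merged, groups, "health_loss", "total"),
    time_loss = group_aggregate(merged, groups, "time_loss", "total"),
    total_loss = group_aggregate(merged, groups, "total_loss", "total"),
    population = group_aggregate(merged, groups, "population", "total")
  ))
  ensemble <- NULL
  if (!is.null(dists)) {
    dists$seed <- substream_seed(seed, "montecarlo")
    ensemble <- stage("montecarlo",
                      run_ensemble(dists, scenario, panel, valuation))
  }
  manifest <- list(
    package = "washsim",
    version = as.character(utils::packageVersion("washsim")),
    seed = as.integer(seed),
    n_countries = length(unique(panel$country_id)),
    panel_years = range(panel$year),
    end_year = as.integer(end_year),
    n_clipped = attr(projection, "n_clipped"),
    monte_carlo = !is.null(ensemble),
    n_draws = if (is.null(ensemble)) 0L else nrow(ensemble$draws)
  )
  result <- structure(list(fit = fit, scenario = scenario,
                           projection = projection, losses = ledger,
                           groups = groups, aggregates = aggregates,
                           ensemble = ensemble, manifest = manifest),
                      class = "wash_pipeline")
  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  result
}

# Write all pipeline artifacts as CSV/JSON under out_dir.
write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(as.data.frame(df), file.path(out_dir, name),
                     row.names = FALSE)
  }
  es <- if (inherits(result$fit, "wash_fit")) result$fit$elasticities
        else result$fit
  write_elasticities(es, file.path(out_dir, "elasticities.json"))
  w(result$projection, "projections.csv")
  w(result$losses, "losses.csv")
  w(result$groups, "groups.csv")
  for (nm in names(result$aggregates)) {
    w(result$aggregates[[nm]], paste0("group_", nm, ".csv"))
  }
  if (!is.null(result$ensemble)) {
    w(as.data.frame(result$ensemble$draws), "ensemble_draws.csv")
    for (nm in names(result$ensemble$quantiles)) {
      q <- result$ensemble$quantiles[[nm]]
      qd <- data.frame(year = as.integer(colnames(q)), t(q))
      w(qd, paste0("ensemble_", nm, ".csv"))
    }
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.wash_pipeline <- function(x, ...) {
  cat("<wash_pipeline>\n")
  cat(sprintf("  %d countries, horizon %d, %d group(s) populated\n",
              x$manifest$n_countries, x$manifest$end_year,
              length(unique(x$groups$group))))
  if (x$manifest$monte_carlo) {
    cat(sprintf("  Monte Carlo: %d draws\n", x$manifest$n_draws))
  }
  invisible(x)
}

#' Summarize a pipeline run as per-group tables
#'
#' Builds per-group time-series tables (population-weighted mortality rate
#' and collection time; total deaths, health, time and total losses;
#' per-capita losses) from the pipeline aggregates, plus interquartile
#' bands at the horizon when an ensemble is present. When the ensemble is
#' absent the report notes that uncertainty bands are unavailable. With
#' `plot = TRUE` draws the group mortality trajectories (dotted line at
#' the observed/forecast boundary).
#'
#' @param result A `wash_pipeline` from [run_pipeline()].
#' @param plot Draw the group-mortality trajectory plot (default `FALSE`).
#' @return A `wash_report`: list with `tables` (one data frame per field,
#'   years x groups), `bands` (horizon quantiles per output, or `NULL`),
#'   and `notes`.
#' @export
render_report <- function(result, plot = FALSE) {
  stopifnot(inherits(result, "wash_pipeline"))
  tables <- lapply(result$aggregates, function(a) {
    out <- stats::reshape(a[c("group", "year", "value")],
                          idvar = "year", timevar = "group",
                          direction = "wide")
    names(out) <- sub("^value\\.", "group", names(out))
    out[order(out$year), , drop = FALSE]
  })
  pc <- merge(result$aggregates$total_loss,
              result$aggregates$population,
              by = c("group", "year"), suffixes = c("_loss", "_pop"))
  pc$value <- pc$value_loss / pc$value_pop
  tables$total_loss_pc <- {
    out <- stats::reshape(pc[c("group", "year", "value")], idvar = "year",
                          timevar = "group", direction = "wide")
    names(out) <- sub("^value\\.", "group", names(out))
    out[order(out$year), , drop = FALSE]
  }
  notes <- character()
  bands <- NULL
  if (is.null(result$ensemble)) {
    notes <- c(notes, "no Monte Carlo ensemble: uncertainty bands omitted")
  } else {
    bands <- lapply(result$ensemble$quantiles, function(q) q[, ncol(q)])
  }
  if (plot) {
    a <- result$aggregates$mortality_rate
    yrs <- sort(unique(a$year))
    gs <- sort(unique(a$group))
    m <- sapply(gs, function(g) a$value[a$group == g][match(
      yrs, a$year[a$group == g])])
    graphics::matplot(yrs, m, type = "l", lty = 1, lwd = 2,
                      col = grDevices::hcl.colors(max(2L, length(gs)),
                                                  "Dark 3"),
                      xlab = "year",
                      ylab = "WASH mortality (deaths/1,000/yr)")
    graphics::legend("topright", legend = paste("group", gs), lty = 1,
                     lwd = 2,
                     col = grDevices::hcl.colors(max(2L, length(gs)),
                                                 "Dark 3"))
    obs_max <- max(result$projection$year[result$projection$observed])
    graphics::abline(v = obs_max, lty = 3)
  }
  structure(list(tables = tables, bands = bands, notes = notes),
            class = "wash_report")
}

#' @export
print.wash_report <- function(x, ...) {
  cat("<wash_report> tables:", paste(names(x$tables), collapse = ", "), "\n")
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}
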