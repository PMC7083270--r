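# Monte Carlo uncertainty propagation: sample uncertain parameters, rerun
# projection + losses per draw, summarize quantile bands per year, and
# attribute output variance to parameters via squared standardized
# regression coefficients.

#' Describe one parameter distribution
#'
#' @param family `"fixed"`, `"normal"`, `"uniform"` or `"triangular"`.
#' @param value Point value (family `"fixed"`).
#' @param mean,sd Normal location and scale.
#' @param min,max Bounds (uniform, triangular, or truncation of a normal).
#' @param mode Triangular mode.
#' @return A `param_dist` description.
#' @export
param_dist <- function(family = c("fixed", "normal", "uniform", "triangular"),
                       value = NULL, mean = NULL, sd = NULL,
                       min = NULL, max = NULL, mode = NULL) {
  family <- match.arg(family)
  d <- switch(family,
    fixed = {
      stopifnot(is.numeric(value))
      list(family = "fixed", value = value)
    },
    normal = {
      stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0)
      list(family = "normal", mean = mean, sd = sd, min = min, max = max)
    },
    uniform = {
      stopifnot(is.numeric(min), is.numeric(max), min <= max)
      list(family = "uniform", min = min, max = max)
    },
    triangular = {
      if (is.null(mode)) mode <- (min + max) / 2
      stopifnot(min <= mode, mode <= max)
      list(family = "triangular", min = min, max = max, mode = mode)
    })
  structure(d, class = "param_dist")
}

# n quantile-inverted draws from a param_dist (consumes exactly n uniforms
# except for the fixed family, keeping the draw stream stable).
draw_dist <- function(d, n) {
  if (d$family == "fixed") return(rep(d$value, n))
  u <- stats::runif(n)
  switch(d$family,
    normal = {
      if (is.null(d$min) && is.null(d$max)) {
        stats::qnorm(u, d$mean, d$sd)
      } else if (d$sd == 0) {
        rep(d$mean, n)
      } else {
        lo <- stats::pnorm(d$min %||% -Inf, d$mean, d$sd)
        hi <- stats::pnorm(d$max %||% Inf, d$mean, d$sd)
        stats::qnorm(lo + u * (hi - lo), d$mean, d$sd)
      }
    },
    uniform = d$min + u * (d$max - d$min),
    triangular = {
      f <- (d$mode - d$min) / (d$max - d$min)
      ifelse(u < f,
             d$min + sqrt(u * (d$max - d$min) * (d$mode - d$min)),
             d$max - sqrt((1 - u) * (d$max - d$min) * (d$max - d$mode)))
    })
}

#' Derive elasticity sampling distributions from fitted CIs
#'
#' For each named coefficient with a finite 95% confidence interval,
#' builds a normal distribution centred on the point estimate with
#' `sd = (ci_upper - ci_lower) / (2 * 1.96)`, truncated to the CI.
#' Coefficients without a CI are sampled as fixed. Draws may cross zero
#' whenever the CI does — no sign restriction is imposed.
#'
#' @param elasticities An [elasticity_set()] or `wash_fit`.
#' @param params Coefficient names to vary (default: all with a CI).
#' @return Named list of [param_dist()] objects.
#' @export
elasticity_dists <- function(elasticities, params = NULL) {
  if (inherits(elasticities, "wash_fit")) {
    elasticities <- elasticities$elasticities
  }
  stopifnot(inherits(elasticities, "elasticity_set"))
  ent <- elasticities$entries
  if (is.null(params)) {
    params <- names(ent)[vapply(ent, function(e) all(is.finite(e$ci)),
                                logical(1))]
  }
  out <- lapply(params, function(nm) {
    e <- ent[[nm]]
    if (all(is.finite(e$ci)) && diff(e$ci) > 0) {
      param_dist("normal", mean = e$estimate,
                 sd = diff(e$ci) / (2 * stats::qnorm(0.975)),
                 min = e$ci[1], max = e$ci[2])
    } else {
      param_dist("fixed", value = e$estimate)
    }
  })
  stats::setNames(out, params)
}

#' Configure the Monte Carlo parameter space
#'
#' Defaults follow the simulation's sensitivity design: each country's
#' average annual GDP growth rate is drawn from N(0.037, 0.013) — the
#' historical distribution of sub-Saharan growth, 1990-2008 — held constant
#' over the horizon within a draw and independent across countries;
#' elasticities are varied over their fitted 95% confidence intervals; the
#' morbidity fraction is uniform on \[0.10, 0.40\]; the climate-growth
#' coefficient is varied between its lower and upper literature bounds when
#' supplied. 1,000 realisations by default.
#'
#' @param growth A [param_dist()] for per-country growth (default
#'   `normal(0.037, 0.013)`, no truncation).
#' @param elasticities Named list of [param_dist()]s for recursion
#'   coefficients (see [elasticity_dists()]); empty means all fixed.
#' @param climate_gdp_coeff Optional [param_dist()] for the climate-growth
#'   coefficient.
#' @param f_morb A [param_dist()] for the morbidity fraction (default
#'   uniform on \[0.10, 0.40\]).
#' @param n_draws Number of realisations (default 1000).
#' @param seed Integer RNG seed.
#' @return An object of class `parameter_distributions`.
#' @export
parameter_distributions <- function(growth = param_dist("normal",
                                                        mean = 0.037,
                                                        sd = 0.013),
                                    elasticities = list(),
                                    climate_gdp_coeff = NULL,
                                    f_morb = param_dist("uniform",
                                                        min = 0.10,
                                                        max = 0.40),
                                    n_draws = 1000L,
                                    seed = 1L) {
  stopifnot(inherits(growth, "param_dist"), n_draws >= 1)
  stopifnot(all(vapply(elasticities, inherits, logical(1), "param_dist")))
  unknown <- setdiff(names(elasticities), elasticity_names())
  if (length(unknown)) {
    stop("unknown elasticity name(s) in distributions: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(growth = growth, elasticities = elasticities,
                 climate_gdp_coeff = climate_gdp_coeff, f_morb = f_morb,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "parameter_distributions")
}

#' Sample the Monte Carlo parameter matrix
#'
#' One row per draw. Growth rates are drawn independently per country
#' (columns `growth_<country_id>`); elasticity, climate and morbidity
#' parameters get one column each. Reproducible: the same seed yields the
#' same matrix.
#'
#' @param dists A [parameter_distributions()].
#' @param countries Character vector of country ids needing growth draws
#'   (may be empty).
#' @param seed Optional override of `dists$seed`.
#' @return Numeric matrix `n_draws x n_params` with named columns.
#' @export
sample_parameters <- function(dists, countries = character(), seed = NULL) {
  stopifnot(inherits(dists, "parameter_distributions"))
  n <- dists$n_draws
  with_seed(seed %||% dists$seed, {
    cols <- list()
    for (cid in countries) {
      cols[[paste0("growth_", cid)]] <- draw_dist(dists$growth, n)
    }
    for (nm in names(dists$elasticities)) {
      cols[[nm]] <- draw_dist(dists$elasticities[[nm]], n)
    }
    if (!is.null(dists$climate_gdp_coeff)) {
      cols[["climate_gdp_coeff"]] <- draw_dist(dists$climate_gdp_coeff, n)
    }
    cols[["f_morb"]] <- draw_dist(dists$f_morb, n)
    do.call(cbind, cols)
  })
}

# Per-year ensemble outputs tracked for every draw.
ensemble_outputs <- c("mortality_rate", "deaths", "collection_time",
                      "health_loss", "time_loss", "total_loss")

# Aggregate one projection + ledger into per-year output rows
# (population-weighted means for intensive fields, sums for extensive).
summarize_run <- function(proj, ledger, years) {
  agg <- function(x, w = NULL, fun = sum) {
    out <- numeric(length(years))
    for (i in seq_along(years)) {
      sel <- proj$year == years[i]
      out[i] <- if (is.null(w)) fun(x[sel]) else
        stats::weighted.mean(x[sel], w[sel])
    }
    out
  }
  list(mortality_rate = agg(proj$mortality_wash, proj$population),
       deaths = agg(proj$deaths),
       collection_time = agg(proj$collection_time, proj$population),
       health_loss = agg(ledger$health_loss),
       time_loss = agg(ledger$time_loss),
       total_loss = agg(ledger$total_loss))
}

# Apply one draw (named vector) to scenario/valuation copies.
apply_draw <- function(draw, scenario, valuation, baseline) {
  es <- scenario$elasticities
  for (nm in intersect(names(draw), elasticity_names())) {
    if (is.null(es$entries[[nm]])) {
      es$entries[[nm]] <- list(estimate = unname(draw[nm]), se = NA_real_,
                               ci = c(NA_real_, NA_real_))
    } else {
      es$entries[[nm]]$estimate <- unname(draw[nm])
    }
  }
  scenario$elasticities <- es
  if ("climate_gdp_coeff" %in% names(draw)) {
    scenario$climate_gdp_coeff <- unname(draw["climate_gdp_coeff"])
  }
  g_cols <- grep("^growth_", names(draw), value = TRUE)
  if (length(g_cols)) {
    base <- panel_baseline(baseline)
    paths <- scenario$paths
    for (gc in g_cols) {
      cid <- sub("^growth_", "", gc)
      b <- base[base$country_id == cid, ]
      sel <- paths$country_id == cid
      paths$gdp_pc[sel] <- b$gdp_pc * exp(unname(draw[gc]) *
                                            (paths$year[sel] - b$year))
    }
    scenario$paths <- paths
  }
  if ("f_morb" %in% names(draw)) valuation$f_morb <- unname(draw["f_morb"])
  list(scenario = scenario, valuation = valuation)
}

#' Run the Monte Carlo ensemble
#'
#' Draws the parameter matrix, then for each realisation overrides the
#' sampled growth rates (rebuilding each country's GDP path from its
#' baseline level), elasticities, climate coefficient and morbidity
#' fraction, reruns [run_projection()] and [compute_losses()], and records
#' region-aggregated per-year outputs (population-weighted mortality rate
#' and collection time; summed deaths and losses). A failing draw is
#' recorded and skipped with a warning, never silently dropped.
#'
#' @param dists A [parameter_distributions()].
#' @param scenario A [scenario_config()] (the base case).
#' @param baseline A [wash_panel].
#' @param valuation A [valuation_config()].
#' @param probs Quantile probabilities summarized per year (default the
#'   interquartile band plus the median).
#' @return An `ensemble_summary`: list with `draws` (parameter matrix),
#'   `years`, `outputs` (list of `n_draws x n_years` matrices), `quantiles`
#'   (list of `length(probs) x n_years` matrices, pointwise per year),
#'   `base` (base-case output series), and `failed` (indices and messages
#'   of skipped draws).
#' @export
run_ensemble <- function(dists, scenario, baseline, valuation,
                         probs = c(0.25, 0.5, 0.75)) {
  stopifnot(inherits(dists, "parameter_distributions"),
            inherits(scenario, "scenario_config"),
            inherits(valuation, "valuation_config"))
  probs <- sort(probs)
  countries <- sort(unique(scenario$paths$country_id))
  draws <- sample_parameters(dists, countries)
  years <- seq(min(panel_baseline(baseline)$year), scenario$end_year)
  base_proj <- run_projection(scenario, baseline)
  years <- sort(unique(base_proj$year))
  base_out <- summarize_run(base_proj, compute_losses(base_proj, baseline,
                                                      valuation), years)
  n <- nrow(draws)
  outputs <- lapply(ensemble_outputs, function(o)
    matrix(NA_real_, n, length(years)))
  names(outputs) <- ensemble_outputs
  failed <- list()
  for (i in seq_len(n)) {
    res <- tryCatch({
      mod <- apply_draw(draws[i, ], scenario, valuation, baseline)
      proj <- run_projection(mod$scenario, baseline)
      summarize_run(proj, compute_losses(proj, baseline, mod$valuation),
                    years)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[[length(failed) + 1L]] <- list(draw = i,
                                            message = conditionMessage(res))
      next
    }
    for (o in ensemble_outputs) outputs[[o]][i, ] <- res[[o]]
  }
  if (length(failed)) {
    warning(length(failed), " of ", n, " draws failed and were skipped",
            call. = FALSE)
  }
  quantiles <- lapply(outputs, function(m) {
    q <- apply(m, 2, stats::quantile, probs = probs, na.rm = TRUE)
    q <- matrix(q, nrow = length(probs),
                dimnames = list(paste0("q", probs * 100), years))
    q
  })
  structure(list(draws = draws, years = years, outputs = outputs,
                 quantiles = quantiles, base = base_out, probs = probs,
                 failed = failed),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary> %d draws, %d failed, years %d-%d\n",
              nrow(x$draws), length(x$failed), min(x$years), max(x$years)))
  h <- x$quantiles$mortality_rate[, ncol(x$quantiles$mortality_rate)]
  cat(sprintf("mortality rate at horizon: %s\n",
              paste(sprintf("%s=%.3f", names(h), h), collapse = ", ")))
  invisible(x)
}

#' Variance decomposition of a Monte Carlo output
#'
#' Regresses the output on the sampled parameters and attributes variance
#' by squared standardized regression coefficients (SRC^2):
#' `share_j = (b_j * sd(x_j) / sd(y))^2`. For a near-linear simulator the
#' shares sum to the regression R^2 (<= 1, with equality for an exactly
#' linear model); the unexplained remainder is reported as the residual
#' share. Constant (fixed-parameter) columns are excluded.
#'
#' @param draws Parameter matrix (rows align with `output`).
#' @param output Numeric vector, one entry per draw (e.g. horizon-year
#'   mortality per realisation).
#' @return A `variance_decomposition`: list with `shares` (named, in
#'   \[0, 1\]), `residual` (1 - R^2), and `r_squared`.
#' @export
variance_decomposition <- function(draws, output) {
  stopifnot(nrow(draws) == length(output), nrow(draws) > ncol(draws))
  keep <- !is.na(output)
  draws <- draws[keep, , drop = FALSE]
  output <- output[keep]
  sds <- apply(draws, 2, stats::sd)
  active <- sds > 0
  X <- draws[, active, drop = FALSE]
  if (ncol(X) == 0L || stats::sd(output) == 0) {
    shares <- stats::setNames(rep(0, ncol(draws)), colnames(draws))
    return(structure(list(shares = shares, residual = 1, r_squared = 0),
                     class = "variance_decomposition"))
  }
  qr_x <- qr(scale(X))
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("collinear parameter column(s): ", paste(dropped, collapse = ", "),
         call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, X), output)
  b <- fit$coefficients[-1]
  src2 <- (b * sds[active] / stats::sd(output))^2
  shares <- stats::setNames(rep(0, ncol(draws)), colnames(draws))
  shares[names(src2)] <- src2
  r2 <- 1 - sum(fit$residuals^2) / sum((output - mean(output))^2)
  structure(list(shares = shares, residual = max(0, 1 - r2),
                 r_squared = r2),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("Variance shares (SRC^2):\n")
  s <- sort(x$shares, decreasing = TRUE)
  s <- s[s > 0.001]
  for (nm in names(s)) cat(sprintf("  %-24s %5.1f%%\n", nm, 100 * s[nm]))
  cat(sprintf("  %-24s %5.1f%%\n", "(residual)", 100 * x$residual))
  invisible(x)
}
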