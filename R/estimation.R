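# Panel semi-elasticity estimation. Outcomes in natural units are regressed
# on ln(GDP per capita) — "elasticity" throughout means semi-elasticity —
# plus coverage/urbanisation terms and arbitrary named controls. Default
# estimator is pooled least squares with country-clustered robust standard
# errors; a one-way random-effects (random country intercept) estimator is
# available behind `estimator = "re"`.

# Fit one equation and package the requested coefficients as an
# elasticity_set with cluster-robust (or RE) SEs and 95% CIs.
fit_equation <- function(data, response, terms, rename, controls,
                         estimator, label) {
  vars <- c(response, terms, controls, "country_id")
  miss <- setdiff(vars, names(data))
  if (length(miss)) {
    stop(label, ": column(s) not in panel: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keep <- stats::complete.cases(data[vars])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(label, ": dropped ", n_dropped,
            " incomplete row(s) listwise")
  }
  d <- data[keep, vars, drop = FALSE]
  rhs <- c(terms, controls)
  if (nrow(d) < length(rhs) + 2L) {
    stop(label, ": insufficient observations (", nrow(d),
         ") to estimate ", length(rhs) + 1L, " coefficients", call. = FALSE)
  }
  fml <- stats::reformulate(rhs, response = response)
  if (estimator == "re") {
    if (!requireNamespace("lme4", quietly = TRUE)) {
      stop("estimator = \"re\" requires the lme4 package", call. = FALSE)
    }
    fit <- lme4::lmer(stats::update(fml, . ~ . + (1 | country_id)), data = d,
                      REML = TRUE)
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    crit <- stats::qnorm(0.975)
    r2 <- stats::cor(stats::fitted(fit), d[[response]])^2
    sig <- stats::sigma(fit)
  } else {
    fit <- stats::lm(fml, data = d)
    est <- stats::coef(fit)
    # suppressWarnings: sandwich's bread() warns on the zero-residual fits
    # that noise-free validation panels produce by design
    vc <- suppressWarnings(
      sandwich::vcovCL(fit, cluster = d$country_id, type = "HC1"))
    se <- sqrt(diag(vc))
    crit <- stats::qt(0.975, df = max(1L, length(unique(d$country_id)) - 1L))
    # noise-free validation panels fit exactly; the R^2 itself is still valid
    r2 <- suppressWarnings(summary(fit)$r.squared)
    sig <- stats::sigma(fit)
  }
  entry <- function(nm) {
    list(estimate = unname(est[nm]), se = unname(se[nm]),
         ci = unname(est[nm] + c(-1, 1) * crit * se[nm]))
  }
  core <- stats::setNames(lapply(names(rename), entry), unname(rename))
  ctrl_entries <- stats::setNames(lapply(controls, entry), controls)
  es <- do.call(elasticity_set, c(core, list(controls = ctrl_entries)))
  report <- list(equation = label, n_obs = nrow(d),
                 n_countries = length(unique(d$country_id)),
                 n_dropped = n_dropped, r_squared = r2, sigma = sig,
                 estimator = estimator, formula = deparse(fml))
  list(elasticities = es, report = report, model = fit)
}

# Previous-period value within country (records assumed sorted by year
# within country, as wash_panel guarantees). The lag is one panel period.
lag_by_country <- function(x, country) {
  out <- c(NA, x[-length(x)])
  out[c(TRUE, country[-1] != country[-length(country)])] <- NA
  out
}

#' Fit the coverage equation
#'
#' Regresses water coverage (fraction) on ln(previous-period GDP per
#' capita), urban share, and optional controls, for either the improved or
#' the piped definition. Income enters lagged one panel period. Standard
#' errors are clustered by country under the default pooled estimator.
#'
#' @param panel A [wash_panel].
#' @param definition `"improved"` or `"piped"`.
#' @param controls Character vector of additional panel column names.
#' @param estimator `"pooled"` (least squares, country-clustered robust
#'   SEs) or `"re"` (random country intercept via lme4).
#' @return List with `elasticities` (partial [elasticity_set()] holding
#'   `kappa0_*`, `kappa_Y_*`, `kappa_urban_*` for the chosen definition),
#'   `report` (fit summary), and `model` (the underlying fit).
#' @export
fit_coverage_model <- function(panel, definition = c("improved", "piped"),
                               controls = character(),
                               estimator = c("pooled", "re")) {
  stopifnot(inherits(panel, "wash_panel"))
  definition <- match.arg(definition)
  estimator <- match.arg(estimator)
  d <- as.data.frame(panel)
  per_country <- table(d$country_id[!is.na(d$gdp_pc)])
  if (!any(per_country >= 2)) {
    stop("coverage fit needs >= 2 periods per country to build the income lag",
         call. = FALSE)
  }
  d$ln_gdp_lag <- log(lag_by_country(d$gdp_pc, d$country_id))
  response <- paste0("coverage_", definition)
  rename <- c("(Intercept)" = paste0("kappa0_", definition),
              ln_gdp_lag = paste0("kappa_Y_", definition),
              urban_share = paste0("kappa_urban_", definition))
  fit_equation(d, response, c("ln_gdp_lag", "urban_share"), rename,
               controls, estimator, paste0("coverage[", definition, "]"))
}

#' Fit the mortality equation
#'
#' Regresses the WASH mortality rate (deaths/1,000/year) on ln(GDP per
#' capita), improved coverage, piped coverage, optionally temperature, and
#' controls. Both coverage definitions enter jointly; a near-collinear pair
#' (piped tracking improved) triggers a warning with the model-matrix
#' condition number. When no usable temperature column is present the
#' returned set omits `gamma_temp` and the fit flags it `"external"` — the
#' projection stage then expects it from the literature-sourced scenario
#' configuration.
#'
#' @inheritParams fit_coverage_model
#' @param include_temperature Include the temperature regressor when the
#'   column has data (default `TRUE`).
#' @return List with `elasticities` (`alpha0`, `alpha_Y`, `beta_imp`,
#'   `beta_piped`, optionally `gamma_temp`), `report`, `model`, and
#'   `external` (character vector of coefficients left to external
#'   sources).
#' @export
fit_mortality_model <- function(panel, controls = character(),
                                include_temperature = TRUE,
                                estimator = c("pooled", "re")) {
  stopifnot(inherits(panel, "wash_panel"))
  estimator <- match.arg(estimator)
  d <- as.data.frame(panel)
  d$ln_gdp <- log(d$gdp_pc)
  r <- stats::cor(d$coverage_improved, d$coverage_piped,
                  use = "complete.obs")
  terms <- c("ln_gdp", "coverage_improved", "coverage_piped")
  rename <- c("(Intercept)" = "alpha0", ln_gdp = "alpha_Y",
              coverage_improved = "beta_imp", coverage_piped = "beta_piped")
  has_temp <- include_temperature && "temperature" %in% names(d) &&
    any(!is.na(d$temperature)) &&
    stats::sd(d$temperature, na.rm = TRUE) > 0
  if (has_temp) {
    terms <- c(terms, "temperature")
    rename <- c(rename, temperature = "gamma_temp")
  }
  if (!is.na(r) && abs(r) > 0.999) {
    X <- as.matrix(stats::na.omit(d[c("coverage_improved", "coverage_piped")]))
    warning(sprintf(
      "improved and piped coverage are nearly collinear (r = %.5f, condition number %.3g); beta_imp/beta_piped are unstable",
      r, kappa(cbind(1, X))), call. = FALSE)
  }
  out <- fit_equation(d, "mortality_wash", terms, rename, controls,
                      estimator, "mortality")
  out$external <- if (has_temp) character() else "gamma_temp"
  out
}

#' Fit the collection-time equation
#'
#' Regresses average one-way water-collection time (minutes) on ln(GDP per
#' capita) and urban share, with survey-source indicator variables and any
#' other covariates absorbed as named controls.
#'
#' @inheritParams fit_coverage_model
#' @return List with `elasticities` (`theta0`, `theta_Y`, `gamma_urban`),
#'   `report`, and `model`.
#' @export
fit_collection_model <- function(panel, controls = character(),
                                 estimator = c("pooled", "re")) {
  stopifnot(inherits(panel, "wash_panel"))
  estimator <- match.arg(estimator)
  d <- as.data.frame(panel)
  if (all(is.na(d$collection_time))) {
    stop("all collection times are missing; cannot fit the time equation",
         call. = FALSE)
  }
  d$ln_gdp <- log(d$gdp_pc)
  rename <- c("(Intercept)" = "theta0", ln_gdp = "theta_Y",
              urban_share = "gamma_urban")
  fit_equation(d, "collection_time", c("ln_gdp", "urban_share"), rename,
               controls, estimator, "collection_time")
}

#' Fit all simulation elasticities from a panel
#'
#' Convenience wrapper fitting the two coverage equations, the mortality
#' equation and the collection-time equation, and merging the coefficients
#' into one [elasticity_set()] ready for [run_projection()].
#'
#' @inheritParams fit_coverage_model
#' @param controls Either a single character vector of control columns used
#'   in every equation, or a named list with elements `coverage`,
#'   `mortality`, `time`.
#' @param include_temperature Passed to [fit_mortality_model()].
#' @return An object of class `wash_fit` with elements `elasticities`
#'   (merged set), `fits` (the four per-equation fit objects), `reports`,
#'   and `external`.
#' @examples
#' panel <- generate_panel(synth_config(n_countries = 10, seed = 7))
#' fit <- wash_fit(panel)
#' coef(fit)["kappa_Y_improved"]
#' @export
wash_fit <- function(panel, controls = character(),
                     include_temperature = TRUE,
                     estimator = c("pooled", "re")) {
  estimator <- match.arg(estimator)
  if (!is.list(controls)) {
    controls <- list(coverage = controls, mortality = controls,
                     time = controls)
  }
  controls <- utils::modifyList(
    list(coverage = character(), mortality = character(),
         time = character()), controls)
  fits <- list(
    coverage_improved = fit_coverage_model(panel, "improved",
                                           controls$coverage, estimator),
    coverage_piped = fit_coverage_model(panel, "piped",
                                        controls$coverage, estimator),
    mortality = fit_mortality_model(panel, controls$mortality,
                                    include_temperature, estimator),
    collection = fit_collection_model(panel, controls$time, estimator)
  )
  es <- do.call(merge_elasticities, lapply(fits, `[[`, "elasticities"))
  structure(list(elasticities = es,
                 fits = fits,
                 reports = lapply(fits, `[[`, "report"),
                 external = fits$mortality$external),
            class = "wash_fit")
}

#' @export
coef.wash_fit <- function(object, ...) coef(object$elasticities)

#' @export
confint.wash_fit <- function(object, parm, level = 0.95, ...) {
  confint(object$elasticities, parm = parm, level = level, ...)
}

#' @export
print.wash_fit <- function(x, ...) {
  cat("WASH simulation elasticities (", x$reports[[1]]$estimator,
      " estimator)\n", sep = "")
  print(x$elasticities)
  if (length(x$external)) {
    cat("external (not fitted):", paste(x$external, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.wash_fit <- function(object, ...) {
  rep_df <- do.call(rbind, lapply(object$reports, function(r) {
    data.frame(equation = r$equation, n_obs = r$n_obs,
               n_countries = r$n_countries, dropped = r$n_dropped,
               r_squared = r$r_squared, sigma = r$sigma,
               stringsAsFactors = FALSE)
  }))
  rownames(rep_df) <- NULL
  structure(list(elasticities = object$elasticities, reports = rep_df,
                 external = object$external),
            class = "summary.wash_fit")
}

#' @export
print.summary.wash_fit <- function(x, ...) {
  print(x$elasticities)
  cat("\nPer-equation fit:\n")
  print(x$reports, digits = 4)
  invisible(x)
}
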