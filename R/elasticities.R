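# Semi-elasticity container shared by the generator, the panel fits, the
# forward recursions and the Monte Carlo sampler.

# Canonical parameter names. "kappa" terms drive the two coverage
# recursions, "alpha/beta/gamma_temp" the mortality recursion,
# "theta/gamma_urban" the collection-time recursion. Intercepts are kept so
# the generator and the structural-recovery tests can reproduce levels.
elasticity_names <- function() {
  c("kappa0_improved", "kappa_Y_improved", "kappa_urban_improved",
    "kappa0_piped", "kappa_Y_piped", "kappa_urban_piped",
    "alpha0", "alpha_Y", "beta_imp", "beta_piped", "gamma_temp",
    "theta0", "theta_Y", "gamma_urban")
}

#' Construct a set of semi-elasticities
#'
#' Bundles the coefficients consumed by the forward recursions, each with an
#' optional standard error and 95% confidence interval. Units: `kappa_Y_*`
#' are coverage-fraction change per unit change in ln(GDP per capita);
#' `kappa_urban_*` coverage change per unit change in urban share;
#' `alpha_Y` mortality change (deaths/1,000) per unit change in ln GDP;
#' `beta_imp` / `beta_piped` mortality change per unit change in the
#' respective coverage fraction; `gamma_temp` mortality change per degree C;
#' `theta_Y` collection-minutes change per unit change in ln GDP;
#' `gamma_urban` minutes change per unit change in urban share.
#'
#' `gamma_temp` is typically sourced from external literature rather than a
#' panel fit; when absent from a fitted set it is flagged `"external"`.
#'
#' @param ... Named coefficients. Each may be a single number (point
#'   estimate) or a list with elements `estimate`, `se`, `ci` (length-2).
#' @param controls Optional named list of control-coefficient entries.
#' @return An object of class `elasticity_set`.
#' @examples
#' es <- elasticity_set(kappa_Y_improved = 0.05, kappa_urban_improved = 0.2)
#' coef(es)
#' @export
elasticity_set <- function(..., controls = list()) {
  entries <- list(...)
  if (length(entries) == 1L && is.list(entries[[1]]) &&
      is.null(entries[[1]]$estimate) && !is.null(names(entries[[1]]))) {
    entries <- entries[[1]]
  }
  if (is.null(names(entries)) || any(names(entries) == "")) {
    stop("all elasticities must be named", call. = FALSE)
  }
  unknown <- setdiff(names(entries), elasticity_names())
  if (length(unknown)) {
    stop("unknown elasticity name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  entries <- lapply(entries, function(e) {
    if (is.numeric(e) && length(e) == 1L) {
      e <- list(estimate = unname(e), se = NA_real_,
                ci = c(NA_real_, NA_real_))
    }
    stopifnot(is.list(e), !is.null(e$estimate))
    if (is.null(e$se)) e$se <- NA_real_
    if (is.null(e$ci)) e$ci <- c(NA_real_, NA_real_)
    if (!all(is.na(e$ci))) {
      if (e$ci[1] > e$estimate + 1e-12 || e$ci[2] < e$estimate - 1e-12) {
        stop("confidence interval does not bracket the point estimate",
             call. = FALSE)
      }
    }
    e[c("estimate", "se", "ci")]
  })
  structure(list(entries = entries, controls = controls),
            class = "elasticity_set")
}

#' @export
coef.elasticity_set <- function(object, ...) {
  vapply(object$entries, function(e) e$estimate, numeric(1))
}

#' @export
confint.elasticity_set <- function(object, parm, level = 0.95, ...) {
  ci <- t(vapply(object$entries, function(e) e$ci, numeric(2)))
  colnames(ci) <- c("2.5 %", "97.5 %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.elasticity_set <- function(x, ...) {
  cat("<elasticity_set>\n")
  for (nm in names(x$entries)) {
    e <- x$entries[[nm]]
    cat(sprintf("  %-22s %+.6g", nm, e$estimate))
    if (!is.na(e$se)) cat(sprintf("  (se %.3g, 95%% CI [%.4g, %.4g])",
                                  e$se, e$ci[1], e$ci[2]))
    cat("\n")
  }
  if (length(x$controls)) {
    cat("  controls:", paste(names(x$controls), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Merge partial elasticity sets
#'
#' Later sets override earlier ones on shared names; controls are
#' concatenated. Used to assemble the full set from per-equation fits.
#'
#' @param ... `elasticity_set` objects.
#' @return A single `elasticity_set`.
#' @export
merge_elasticities <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, inherits, logical(1), "elasticity_set")))
  entries <- list()
  controls <- list()
  for (s in sets) {
    entries[names(s$entries)] <- s$entries
    controls <- c(controls, s$controls)
  }
  out <- structure(list(entries = entries, controls = controls),
                   class = "elasticity_set")
  out
}

# Point estimate by name; `default` when absent (e.g. gamma_temp external).
ela <- function(es, name, default = NULL) {
  e <- es$entries[[name]]
  if (is.null(e)) {
    if (is.null(default)) stop("elasticity '", name, "' is not available",
                               call. = FALSE)
    return(default)
  }
  e$estimate
}

#' Serialize / deserialize an elasticity set as JSON
#'
#' @param es An `elasticity_set`.
#' @param path File path.
#' @return `write_elasticities` returns `path` invisibly;
#'   `read_elasticities` returns an `elasticity_set`.
#' @export
write_elasticities <- function(es, path) {
  stopifnot(inherits(es, "elasticity_set"))
  jsonlite::write_json(
    list(entries = es$entries, controls = es$controls), path,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_elasticities
#' @export
read_elasticities <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  entries <- lapply(raw$entries, function(e) {
    list(estimate = as.numeric(e$estimate),
         se = if (is.null(e$se)) NA_real_ else as.numeric(e$se),
         ci = if (is.null(e$ci)) c(NA_real_, NA_real_) else as.numeric(e$ci))
  })
  structure(list(entries = entries,
                 controls = if (is.null(raw$controls)) list() else raw$controls),
            class = "elasticity_set")
}
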