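# Trajectory grouping: countries are placed into four groups by their
# baseline (last observed) WASH mortality rate and the base-case projected
# rate at the terminal year, then aggregated with population weights.

#' Grouping thresholds
#'
#' Defaults encode the narrative definitions of the four trajectory
#' groups: group 1 starts high (baseline at or above `moderate_baseline`)
#' and stays high (terminal at or above `terminal_high`); group 2 is the
#' moderate/slow-decline remainder; group 3 starts moderate (between
#' `low_baseline` and `moderate_baseline`) and declines to negligible
#' (below `negligible`); group 4 starts low (below `low_baseline`). All in
#' deaths per 1,000 per year.
#'
#' @param low_baseline Default 0.5.
#' @param moderate_baseline Default 1.0.
#' @param negligible Default 0.1.
#' @param terminal_high Default 1.0.
#' @param terminal_year Year at which the terminal rate is read
#'   (default 2050).
#' @return An object of class `group_thresholds`.
#' @export
group_thresholds <- function(low_baseline = 0.5, moderate_baseline = 1.0,
                             negligible = 0.1, terminal_high = 1.0,
                             terminal_year = 2050L) {
  if (!(negligible < low_baseline && low_baseline < moderate_baseline)) {
    stop("need negligible < low_baseline < moderate_baseline", call. = FALSE)
  }
  if (terminal_high <= negligible) {
    stop("need terminal_high > negligible", call. = FALSE)
  }
  structure(list(low_baseline = low_baseline,
                 moderate_baseline = moderate_baseline,
                 negligible = negligible, terminal_high = terminal_high,
                 terminal_year = as.integer(terminal_year)),
            class = "group_thresholds")
}

#' Classify a country's mortality trajectory
#'
#' Deterministic, total rule on (baseline rate, terminal rate): group 4 if
#' the baseline is below `low_baseline`; group 3 if the baseline is
#' moderate (in \[`low_baseline`, `moderate_baseline`)) and the terminal
#' rate falls below `negligible`; group 1 if the baseline is at or above
#' `moderate_baseline` and the terminal rate at or above `terminal_high`;
#' group 2 otherwise. Vectorized.
#'
#' @param baseline_rate,terminal_rate Deaths per 1,000 per year,
#'   nonnegative.
#' @param thresholds A [group_thresholds()].
#' @return Integer group(s) in 1:4.
#' @examples
#' th <- group_thresholds()
#' classify_country(2.0, 1.5, th)   # 1: high, staying high
#' classify_country(1.2, 0.5, th)   # 2: moderate, slow decline
#' classify_country(0.4, 0.05, th)  # 4: low throughout
#' @export
classify_country <- function(baseline_rate, terminal_rate,
                             thresholds = group_thresholds()) {
  stopifnot(inherits(thresholds, "group_thresholds"),
            all(baseline_rate >= 0), all(terminal_rate >= 0),
            length(baseline_rate) == length(terminal_rate))
  th <- thresholds
  ifelse(baseline_rate < th$low_baseline, 4L,
    ifelse(baseline_rate < th$moderate_baseline & terminal_rate < th$negligible,
           3L,
      ifelse(baseline_rate >= th$moderate_baseline &
               terminal_rate >= th$terminal_high, 1L, 2L)))
}

#' Assign every projected country to a trajectory group
#'
#' Baseline rate is the rate at each country's last observed year
#' (`observed` rows of the projection); terminal rate is the base-case
#' projected rate at `thresholds$terminal_year`.
#'
#' @param projection A `wash_projection` from [run_projection()].
#' @param thresholds A [group_thresholds()].
#' @return A `group_assignment` data frame: `country_id`, `group`,
#'   `baseline_rate`, `terminal_rate`, plus the thresholds used as an
#'   attribute.
#' @export
classify_panel <- function(projection, thresholds = group_thresholds()) {
  stopifnot(inherits(projection, "wash_projection"))
  parts <- split(as.data.frame(projection), projection$country_id)
  rows <- lapply(parts, function(d) {
    obs <- d[d$observed, , drop = FALSE]
    b <- obs$mortality_wash[which.max(obs$year)]
    tsel <- d$year == thresholds$terminal_year
    if (!any(tsel)) {
      stop("projection for ", d$country_id[1], " does not reach terminal year ",
           thresholds$terminal_year, call. = FALSE)
    }
    data.frame(country_id = d$country_id[1], baseline_rate = b,
               terminal_rate = d$mortality_wash[tsel],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$group <- classify_country(out$baseline_rate, out$terminal_rate,
                                thresholds)
  out <- out[c("country_id", "group", "baseline_rate", "terminal_rate")]
  structure(out, thresholds = unclass(thresholds),
            class = c("group_assignment", "data.frame"))
}

#' Population-weighted group aggregates
#'
#' For intensive fields (rates, times, per-capita losses) returns the
#' population-weighted mean per (group, year); for extensive fields
#' (deaths, losses, population) returns the group total. Weights are the
#' same-year populations.
#'
#' @param results A `wash_projection` or a data frame carrying
#'   `country_id`, `year`, `population` and the requested field (e.g. a
#'   projection merged with a loss ledger).
#' @param assignment A `group_assignment` (or data frame with `country_id`
#'   and `group`) covering every country in `results`.
#' @param field Column to aggregate.
#' @param type `"weighted_mean"` (default for intensive fields) or
#'   `"total"`.
#' @return Data frame `group`, `year`, `value`, `population` (group total
#'   population that year).
#' @export
group_aggregate <- function(results, assignment, field,
                            type = c("weighted_mean", "total")) {
  type <- match.arg(type)
  stopifnot(is.data.frame(results), field %in% names(results),
            "population" %in% names(results))
  idx <- match(results$country_id, assignment$country_id)
  if (anyNA(idx)) {
    stop("no group assignment for country: ",
         paste(unique(results$country_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  g <- assignment$group[idx]
  key <- interaction(g, results$year, drop = TRUE)
  pop <- tapply(results$population, key, sum)
  value <- if (type == "weighted_mean") {
    tapply(results[[field]] * results$population, key, sum) / pop
  } else {
    tapply(results[[field]], key, sum)
  }
  parts <- strsplit(names(pop), ".", fixed = TRUE)
  out <- data.frame(group = as.integer(vapply(parts, `[`, "", 1)),
                    year = as.integer(vapply(parts, `[`, "", 2)),
                    value = as.numeric(value),
                    population = as.numeric(pop))
  out <- out[order(out$group, out$year), ]
  rownames(out) <- NULL
  out
}
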