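# Country-year panel container and CSV I/O.

#' Required panel columns
#'
#' Canonical column names of a country-year panel, in the stable order used
#' by [write_panel()].
#'
#' @return Character vector of column names.
#' @export
panel_columns <- function() {
  c("country_id", "year", "gdp_pc", "population", "urban_share",
    "coverage_improved", "coverage_piped", "mortality_wash",
    "collection_time", "temperature", "income_share_b80", "household_size")
}

# Columns that must be present and non-NA for a row to be structurally valid.
.mandatory_cols <- c("country_id", "year", "gdp_pc", "population",
                     "urban_share", "coverage_improved", "coverage_piped")

#' Construct a country-year panel
#'
#' A `wash_panel` is a validated data frame with one row per (country, year)
#' observation. Core fields use fixed units: `gdp_pc` in constant (1990
#' international) dollars per person, `population` in persons, `urban_share`
#' and both coverage fields as fractions in \[0, 1\], `mortality_wash` in
#' WASH-attributable deaths per 1,000 persons per year, `collection_time` in
#' average one-way minutes per trip, `temperature` in degrees C (scenario
#' level or anomaly), `income_share_b80` as the fraction of GDP held by the
#' bottom 80 percent of the income distribution, and `household_size` in
#' persons per household. Arbitrary control covariates (fertility, literacy,
#' governance scores, survey-source indicators, ...) travel as additional
#' columns prefixed `ctrl_`.
#'
#' Missing covariates are explicit `NA`s; estimation drops incomplete rows
#' listwise and reports the count. Gaps in a country's year sequence are
#' allowed; duplicate (country, year) pairs are not.
#'
#' @param data Data frame holding at least the mandatory columns
#'   (`country_id`, `year`, `gdp_pc`, `population`, `urban_share`,
#'   `coverage_improved`, `coverage_piped`).
#' @param metadata Optional named list of free-form source labels and units.
#' @param validate If `TRUE` (default), run [validate_panel()] and fail on
#'   any violation.
#' @return An object of class `wash_panel` (a data frame).
#' @seealso [validate_panel()], [read_panel()], [write_panel()]
#' @export
wash_panel <- function(data, metadata = list(), validate = TRUE) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.mandatory_cols, names(data))
  if (length(missing_cols)) {
    stop("panel is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(panel_columns(), names(data))) data[[col]] <- NA_real_
  data$country_id <- as.character(data$country_id)
  data$year <- as.integer(data$year)
  ord <- c(panel_columns(), sort(setdiff(names(data), panel_columns())))
  data <- data[order(data$country_id, data$year), ord, drop = FALSE]
  rownames(data) <- NULL
  if (validate) {
    bad <- validate_panel(data)
    if (nrow(bad)) {
      stop("panel validation failed:\n",
           paste(sprintf("  row %d [%s, %s]: %s", bad$row, bad$country_id,
                         bad$year, bad$problem), collapse = "\n"),
           call. = FALSE)
    }
  }
  structure(data, metadata = metadata,
            class = c("wash_panel", "data.frame"))
}

#' Validate a country-year panel
#'
#' Checks every record-level invariant: positivity of `gdp_pc`, `population`
#' and `household_size`; `urban_share`, `coverage_improved`, `coverage_piped`
#' in \[0, 1\]; `income_share_b80` in (0, 1\]; nonnegative `mortality_wash`
#' and `collection_time`; piped coverage never exceeding improved coverage;
#' and uniqueness of (country, year). Every violation is reported
#' individually with its row index; `NA`s in optional fields are not
#' violations.
#'
#' @param data Data frame with panel columns.
#' @return Data frame with columns `row`, `country_id`, `year`, `problem`
#'   (zero rows when the panel is valid).
#' @export
validate_panel <- function(data) {
  viol <- function(idx, problem) {
    if (!length(idx)) return(NULL)
    data.frame(row = idx, country_id = as.character(data$country_id[idx]),
               year = as.character(data$year[idx]), problem = problem,
               stringsAsFactors = FALSE)
  }
  chk <- function(x, ok) which(!is.na(x) & !ok)
  out <- list(
    viol(which(is.na(data$country_id) | data$country_id == ""),
         "country_id missing"),
    viol(which(is.na(data$year)), "year missing"),
    viol(chk(data$gdp_pc, data$gdp_pc > 0), "gdp_pc must be > 0"),
    viol(chk(data$population, data$population > 0), "population must be > 0"),
    viol(chk(data$urban_share, data$urban_share >= 0 & data$urban_share <= 1),
         "urban_share outside [0, 1]"),
    viol(chk(data$coverage_improved,
             data$coverage_improved >= 0 & data$coverage_improved <= 1),
         "coverage_improved outside [0, 1]"),
    viol(chk(data$coverage_piped,
             data$coverage_piped >= 0 & data$coverage_piped <= 1),
         "coverage_piped outside [0, 1]"),
    viol(chk(data$mortality_wash, data$mortality_wash >= 0),
         "mortality_wash must be >= 0"),
    viol(chk(data$collection_time, data$collection_time >= 0),
         "collection_time must be >= 0"),
    viol(chk(data$income_share_b80,
             data$income_share_b80 > 0 & data$income_share_b80 <= 1),
         "income_share_b80 outside (0, 1]"),
    viol(chk(data$household_size, data$household_size > 0),
         "household_size must be > 0"),
    viol(which(!is.na(data$coverage_piped) & !is.na(data$coverage_improved) &
                 data$coverage_piped > data$coverage_improved + 1e-12),
         "coverage_piped exceeds coverage_improved"),
    viol(which(duplicated(data[c("country_id", "year")])),
         "duplicate (country_id, year)")
  )
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(row = integer(), country_id = character(),
                      year = character(), problem = character(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$row), , drop = FALSE]
}

#' Read a panel from CSV
#'
#' Reads an RFC-4180 CSV (UTF-8, header row) into a validated [wash_panel].
#' A `schema` map renames file columns to canonical names, so panels
#' assembled from heterogeneous sources need not be pre-renamed. Coverage
#' and shares may be carried in percent in the file; set
#' `coverage_unit = "percent"` to divide the share-type columns by 100 at
#' the boundary — internally everything is a fraction.
#'
#' @param path Path to a CSV file.
#' @param schema Named character vector mapping canonical column name ->
#'   file column name, e.g. `c(gdp_pc = "GDP.percap")`. Unmapped canonical
#'   names are looked up verbatim.
#' @param coverage_unit `"fraction"` (default) or `"percent"` for the
#'   coverage, urban-share and income-share columns.
#' @return A [wash_panel].
#' @export
read_panel <- function(path, schema = NULL,
                       coverage_unit = c("fraction", "percent")) {
  coverage_unit <- match.arg(coverage_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(raw)) {
        stop("schema maps '", canon, "' to missing column '", src, "'",
             call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing_cols <- setdiff(.mandatory_cols, names(raw))
  if (length(missing_cols)) {
    stop("CSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (coverage_unit == "percent") {
    for (col in c("urban_share", "coverage_improved", "coverage_piped",
                  "income_share_b80")) {
      if (col %in% names(raw)) raw[[col]] <- raw[[col]] / 100
    }
  }
  wash_panel(raw)
}

#' Write a panel to CSV
#'
#' One row per (country, year), canonical columns first in stable order,
#' control columns (`ctrl_`-prefixed) after them alphabetically. Values are
#' written with full double precision so that a write/read round trip
#' reproduces the panel.
#'
#' @param panel A [wash_panel].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "wash_panel"))
  out <- as.data.frame(panel)
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "year"
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  out[out == "nan" | out == "NA"] <- NA
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = ""),
    error = function(e) stop("cannot write panel to '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  invisible(path)
}

#' @export
print.wash_panel <- function(x, ...) {
  cat(sprintf("<wash_panel> %d records, %d countries, years %s-%s\n",
              nrow(x), length(unique(x$country_id)),
              if (nrow(x)) min(x$year) else "-",
              if (nrow(x)) max(x$year) else "-"))
  ctrl <- grep("^ctrl_", names(x), value = TRUE)
  if (length(ctrl)) cat("controls:", paste(ctrl, collapse = ", "), "\n")
  invisible(x)
}

# Latest observed (non-NA mortality) year per country: the simulation
# baseline.
panel_baseline <- function(panel) {
  stopifnot(inherits(panel, "wash_panel"))
  parts <- split(as.data.frame(panel), panel$country_id)
  rows <- lapply(parts, function(d) d[which.max(d$year), , drop = FALSE])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
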