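#' Panel datasets of kindergarten vaccination outcomes
#'
#' A `panel_dataset` holds a state- or county-level panel of school-entry
#' vaccination outcomes (coverage and exemption prevalences, in percentage
#' points on \[0, 100\]) together with unit covariates, the set of treated
#' units and the first post-policy school year. Years are encoded by
#' school-year start, so 2016 denotes the 2016-2017 school year.
#'
#' @param data tibble with one row per unit-year: columns `unit_id`,
#'   `parent_state`, `year`, `population`, plus one numeric column per
#'   outcome. Missing outcome cells are `NA`, never zero.
#' @param level `"state"` or `"county"`.
#' @param treated_units character vector of treated unit ids (nonempty).
#' @param policy_year integer; first school year in which the policy applies.
#' @param covariates optional tibble keyed by `unit_id`, `year` with one
#'   numeric column per covariate.
#' @param outcomes character vector naming the outcome columns of `data`.
#'
#' @return An object of class `panel_dataset`.
#' @export
panel_dataset <- function(data, level = c("state", "county"), treated_units,
                          policy_year, covariates = NULL, outcomes = NULL) {
  level <- match.arg(level)
  data <- tibble::as_tibble(data)
  if (is.null(outcomes)) {
    reserved <- c("unit_id", "parent_state", "year", "population")
    outcomes <- setdiff(names(data), reserved)
  }
  x <- structure(
    list(
      level = level,
      data = data,
      outcomes = outcomes,
      covariates = if (!is.null(covariates)) tibble::as_tibble(covariates),
      treated_units = as.character(treated_units),
      policy_year = as.integer(policy_year)
    ),
    class = "panel_dataset"
  )
  validate_panel(x)
}

#' Validate a panel dataset
#'
#' Checks the structural invariants: unique (unit, year) keys, outcome values
#' inside \[0, 100\] or missing, nonempty treated set drawn from the panel's
#' units, an interior policy year, and (for county panels) a parent state on
#' every record.
#'
#' @param x a `panel_dataset`.
#' @return `x`, invisibly checked.
#' @export
validate_panel <- function(x) {
  stopifnot(inherits(x, "panel_dataset"))
  d <- x$data
  need <- c("unit_id", "parent_state", "year", "population")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    abort(paste0("panel data lacks required column(s): ",
                 paste(miss, collapse = ", ")), "vaxpolicy_schema_error")
  }
  if (!length(x$outcomes) || !all(x$outcomes %in% names(d))) {
    abort("panel must declare at least one outcome column present in the data",
          "vaxpolicy_schema_error")
  }
  key <- paste(d$unit_id, d$year)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(paste0("duplicate (unit_id, year) record: ", dup),
          "vaxpolicy_validation_error")
  }
  for (oc in x$outcomes) {
    v <- d[[oc]]
    bad <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(bad)) {
      i <- bad[1]
      abort(sprintf("outcome '%s' outside [0, 100] at (%s, %d): %g",
                    oc, d$unit_id[i], d$year[i], v[i]),
            "vaxpolicy_validation_error")
    }
  }
  if (!length(x$treated_units)) {
    abort("treated_units must be nonempty", "vaxpolicy_validation_error")
  }
  if (!all(x$treated_units %in% d$unit_id)) {
    abort(paste0("treated unit(s) absent from panel: ",
                 paste(setdiff(x$treated_units, d$unit_id), collapse = ", ")),
          "vaxpolicy_validation_error")
  }
  yrs <- range(d$year)
  if (x$policy_year <= yrs[1] || x$policy_year > yrs[2]) {
    abort(sprintf("policy_year %d must lie in [%d, %d]",
                  x$policy_year, yrs[1] + 1L, yrs[2]),
          "vaxpolicy_validation_error")
  }
  if (x$level == "county" && anyNA(d$parent_state)) {
    abort("county panels require parent_state on every record",
          "vaxpolicy_validation_error")
  }
  x
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf(
    "<panel_dataset> %s level: %d units x years %d-%d, outcomes: %s\n",
    x$level, length(unique(x$data$unit_id)), min(x$data$year),
    max(x$data$year), paste(x$outcomes, collapse = ", ")
  ))
  cat(sprintf("  treated: %s; policy year: %d\n",
              paste(x$treated_units, collapse = ", "), x$policy_year))
  invisible(x)
}

panel_units <- function(panel) unique(panel$data$unit_id)

panel_years <- function(panel) sort(unique(panel$data$year))

# Subset a panel to a set of units, preserving metadata. Treated units not in
# `units` are dropped from the treated set (callers must keep it nonempty).
panel_subset_units <- function(panel, units, treated_units = NULL) {
  panel$data <- panel$data[panel$data$unit_id %in% units, , drop = FALSE]
  if (!is.null(panel$covariates)) {
    panel$covariates <-
      panel$covariates[panel$covariates$unit_id %in% units, , drop = FALSE]
  }
  panel$treated_units <-
    if (is.null(treated_units)) intersect(panel$treated_units, units)
    else as.character(treated_units)
  validate_panel(panel)
}

#' Read a long-format vaccination panel from CSV
#'
#' Expects the long dialect with columns `unit_id, parent_state, level, year,
#' outcome, value, population` (names remappable through `schema`). Empty
#' cells are read as missing and preserved as `NA`; values are validated to
#' lie in \[0, 100\].
#'
#' @param path path to the panel CSV.
#' @param level `"state"` or `"county"`; rows of other levels are rejected.
#' @param treated_units,policy_year passed to [panel_dataset()].
#' @param covariates_path optional CSV of covariates keyed by `unit_id, year`.
#' @param schema named character vector remapping the required logical column
#'   names to the file's column names, e.g. `c(unit_id = "state_abbr")`.
#' @return a [panel_dataset()].
#' @export
read_panel <- function(path, level = c("state", "county"), treated_units,
                       policy_year, covariates_path = NULL, schema = NULL) {
  level <- match.arg(level)
  if (!file.exists(path)) {
    abort(paste0("panel file not found: ", path), "vaxpolicy_io_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  cols <- c(unit_id = "unit_id", parent_state = "parent_state",
            level = "level", year = "year", outcome = "outcome",
            value = "value", population = "population")
  if (!is.null(schema)) cols[names(schema)] <- schema
  miss <- setdiff(unname(cols), names(raw))
  if (length(miss)) {
    abort(paste0("panel CSV lacks required column(s): ",
                 paste(miss, collapse = ", ")), "vaxpolicy_schema_error")
  }
  long <- tibble::tibble(
    unit_id = as.character(raw[[cols["unit_id"]]]),
    parent_state = as.character(raw[[cols["parent_state"]]]),
    level = as.character(raw[[cols["level"]]]),
    year = raw[[cols["year"]]],
    outcome = as.character(raw[[cols["outcome"]]]),
    value = as.numeric(raw[[cols["value"]]]),
    population = as.numeric(raw[[cols["population"]]])
  )
  if (any(long$level != level)) {
    abort(sprintf("panel contains rows with level != '%s'", level),
          "vaxpolicy_validation_error")
  }
  yr <- suppressWarnings(as.integer(long$year))
  if (anyNA(yr)) {
    abort("column 'year' must be integer school-year starts",
          "vaxpolicy_validation_error")
  }
  long$year <- yr
  dup <- duplicated(long[c("unit_id", "year", "outcome")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf("duplicate record for (%s, %d, %s)",
                  long$unit_id[i], long$year[i], long$outcome[i]),
          "vaxpolicy_validation_error")
  }
  wide <- tidyr::pivot_wider(long, id_cols = c("unit_id", "parent_state",
                                               "year", "population"),
                             names_from = "outcome", values_from = "value")
  covs <- NULL
  if (!is.null(covariates_path)) {
    covs <- tibble::as_tibble(
      utils::read.csv(covariates_path, stringsAsFactors = FALSE,
                      na.strings = c("", "NA"))
    )
    if (!all(c("unit_id", "year") %in% names(covs))) {
      abort("covariate CSV must contain columns unit_id and year",
            "vaxpolicy_schema_error")
    }
    covs$unit_id <- as.character(covs$unit_id)
    covs$year <- as.integer(covs$year)
  }
  panel_dataset(wide, level = level, treated_units = treated_units,
                policy_year = policy_year, covariates = covs)
}

#' Write a panel back to the long CSV dialect
#'
#' Inverse of [read_panel()]: one row per (unit, year, outcome), missing
#' values as empty cells.
#'
#' @param panel a `panel_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  long <- tidyr::pivot_longer(panel$data, cols = dplyr::all_of(panel$outcomes),
                              names_to = "outcome", values_to = "value")
  long$level <- panel$level
  long <- long[c("unit_id", "parent_state", "level", "year", "outcome",
                 "value", "population")]
  utils::write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Cleaning reports
#'
#' Records every repair the cleaning operations make: units excluded (with a
#' reason), cells imputed, and county-years whose overall coverage was filled
#' from MMR coverage as a proxy.
#'
#' @param excluded_units tibble with columns `unit_id`, `reason`.
#' @param imputed_cells tibble with columns `unit_id`, `year`, `outcome`.
#' @param proxy_substitutions tibble with columns `unit_id`, `year`.
#' @return an object of class `cleaning_report`.
#' @export
cleaning_report <- function(excluded_units = NULL, imputed_cells = NULL,
                            proxy_substitutions = NULL) {
  empty <- function(...) {
    tpl <- list(...)
    tibble::as_tibble(lapply(tpl, function(cl) vector(cl, 0L)))
  }
  structure(
    list(
      excluded_units = excluded_units %||%
        empty(unit_id = "character", reason = "character"),
      imputed_cells = imputed_cells %||%
        empty(unit_id = "character", year = "integer", outcome = "character"),
      proxy_substitutions = proxy_substitutions %||%
        empty(unit_id = "character", year = "integer")
    ),
    class = "cleaning_report"
  )
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(
    "<cleaning_report> %d unit(s) excluded, %d cell(s) imputed, %d proxy substitution(s)\n",
    nrow(x$excluded_units), nrow(x$imputed_cells), nrow(x$proxy_substitutions)
  ))
  invisible(x)
}

# Concatenate two cleaning reports.
merge_reports <- function(a, b) {
  cleaning_report(
    excluded_units = dplyr::bind_rows(a$excluded_units, b$excluded_units),
    imputed_cells = dplyr::bind_rows(a$imputed_cells, b$imputed_cells),
    proxy_substitutions = dplyr::bind_rows(a$proxy_substitutions,
                                           b$proxy_substitutions)
  )
}
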