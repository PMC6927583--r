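#' Apply county-level inclusion filters and proxy substitution
#'
#' Drops counties whose population falls below `min_population` (the study
#' design restricts to counties of at least 65,000 residents, where covariate
#' data are available) and, for counties that never report overall coverage
#' but do report MMR coverage, fills overall coverage from MMR as a proxy.
#' Proxying is a per-unit decision: a county is either proxied for all of its
#' reported years or not at all, and every filled year is logged so the
#' proxy-free subanalysis can exclude those states later.
#'
#' @param panel a county-level `panel_dataset`.
#' @param min_population inclusion threshold on county population.
#' @param overall,mmr names of the overall-coverage and MMR outcome columns;
#'   proxying is skipped unless both are present.
#' @return list with elements `panel` (filtered) and `report`
#'   (a [cleaning_report()]).
#' @export
apply_county_filters <- function(panel, min_population = 65000,
                                 overall = "overall", mmr = "mmr") {
  validate_panel(panel)
  if (panel$level != "county") {
    abort("apply_county_filters requires a county-level panel",
          "vaxpolicy_level_error")
  }
  if (min_population < 0) {
    abort("min_population must be nonnegative", "vaxpolicy_parameter_error")
  }
  d <- panel$data
  # Unit population: latest non-missing figure.
  pop <- vapply(split(d, d$unit_id), function(u) {
    v <- u$population[order(u$year)]
    v <- v[!is.na(v)]
    if (length(v)) v[length(v)] else NA_real_
  }, numeric(1))
  drop <- names(pop)[!is.na(pop) & pop < min_population]
  report <- cleaning_report(
    excluded_units = tibble::tibble(
      unit_id = drop,
      reason = rep("population_below_threshold", length(drop))
    )
  )
  keep <- setdiff(unique(d$unit_id), drop)
  treated <- intersect(panel$treated_units, keep)
  if (!length(treated)) {
    abort("population filter removed every treated county",
          "vaxpolicy_infeasible_error")
  }
  panel <- panel_subset_units(panel, keep, treated_units = treated)

  if (all(c(overall, mmr) %in% panel$outcomes)) {
    d <- panel$data
    proxied <- vapply(split(d, d$unit_id), function(u) {
      all(is.na(u[[overall]])) && any(!is.na(u[[mmr]]))
    }, logical(1))
    proxied <- names(proxied)[proxied]
    if (length(proxied)) {
      sel <- d$unit_id %in% proxied & !is.na(d[[mmr]])
      d[[overall]][sel] <- d[[mmr]][sel]
      panel$data <- d
      report$proxy_substitutions <- tibble::tibble(
        unit_id = d$unit_id[sel], year = as.integer(d$year[sel])
      )
    }
  }
  list(panel = validate_panel(panel), report = report)
}

#' Impute or exclude missing outcome data
#'
#' Units whose missing fraction for `outcome` exceeds `max_missing_fraction`
#' are excluded from the panel; remaining missing cells are filled by
#' within-unit linear interpolation over year, extending the nearest observed
#' value at the edges. Observed cells are never altered, and after the call
#' the outcome has no missing cells.
#'
#' @param panel a `panel_dataset`.
#' @param outcome outcome column to repair.
#' @param max_missing_fraction tolerated per-unit missing fraction in
#'   \[0, 1\]; default 0.2.
#' @return list with elements `panel` and `report`.
#' @export
handle_missing <- function(panel, outcome, max_missing_fraction = 0.2) {
  validate_panel(panel)
  if (!outcome %in% panel$outcomes) {
    abort(paste0("unknown outcome: ", outcome), "vaxpolicy_name_error")
  }
  if (!is_scalar_number(max_missing_fraction) ||
      max_missing_fraction < 0 || max_missing_fraction > 1) {
    abort("max_missing_fraction must lie in [0, 1]",
          "vaxpolicy_parameter_error")
  }
  d <- panel$data
  frac <- vapply(split(d[[outcome]], d$unit_id), function(v) mean(is.na(v)),
                 numeric(1))
  # A unit with no observed value at all can never be interpolated.
  drop <- names(frac)[frac > max_missing_fraction | frac >= 1]
  report <- cleaning_report(
    excluded_units = tibble::tibble(
      unit_id = drop, reason = rep("missing_above_threshold", length(drop))
    )
  )
  keep <- setdiff(unique(d$unit_id), drop)
  treated <- intersect(panel$treated_units, keep)
  if (!length(treated)) {
    abort("missingness filter removed every treated unit",
          "vaxpolicy_infeasible_error")
  }
  panel <- panel_subset_units(panel, keep, treated_units = treated)
  d <- panel$data
  imputed <- list()
  for (u in unique(d$unit_id)) {
    i <- which(d$unit_id == u)
    i <- i[order(d$year[i])]
    v <- d[[outcome]][i]
    na <- is.na(v)
    if (!any(na)) next
    filled <- stats::approx(d$year[i][!na], v[!na], xout = d$year[i],
                            method = "linear", rule = 2)$y
    d[[outcome]][i[na]] <- filled[na]
    imputed[[u]] <- tibble::tibble(
      unit_id = u, year = as.integer(d$year[i[na]]), outcome = outcome
    )
  }
  if (length(imputed)) report$imputed_cells <- dplyr::bind_rows(imputed)
  panel$data <- d
  list(panel = validate_panel(panel), report = report)
}
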