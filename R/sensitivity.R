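#' Leave-one-out robustness over control units
#'
#' Re-runs the full analysis once per control unit (synthetic control) or
#' control state (DiD), excluding that unit from the pool, to gauge the
#' influence of any single control on the effect size. Infeasible refits are
#' reported with a failure flag rather than dropped.
#'
#' @param panel a `panel_dataset`.
#' @param analysis `"sc"` or `"did"`.
#' @param outcome outcome column.
#' @param predictors SC predictor covariates (analysis = "sc").
#' @param covariates DiD adjustment covariates (analysis = "did").
#' @param treated treated unit id for the SC analysis; defaults to the
#'   panel's single treated unit.
#' @param policy_year first post-policy year.
#' @param ... passed to [fit_synthetic_control()] or [fit_did()].
#' @return an object of class `sensitivity_table` with one row per excluded
#'   control; `auxiliary` carries donor weights (SC) or the CI (DiD).
#' @export
leave_one_out <- function(panel, analysis = c("sc", "did"), outcome,
                          predictors = character(), covariates = character(),
                          treated = NULL, policy_year = panel$policy_year,
                          ...) {
  analysis <- match.arg(analysis)
  validate_panel(panel)
  if (analysis == "sc") {
    treated <- treated %||% panel$treated_units[1]
    controls <- setdiff(panel_units(panel),
                        union(treated, panel$treated_units))
  } else {
    controls <- setdiff(unique(panel$data$parent_state),
                        unique(panel$data$parent_state[
                          panel$data$unit_id %in% panel$treated_units]))
  }
  if (length(controls) < 3) {
    abort("leave-one-out requires at least 3 control units",
          "vaxpolicy_parameter_error")
  }
  rows <- vector("list", length(controls))
  for (i in seq_along(controls)) {
    ex <- controls[i]
    res <- tryCatch({
      if (analysis == "sc") {
        keep <- setdiff(panel_units(panel), ex)
        fit <- fit_synthetic_control(panel_subset_units(panel, keep),
                                     outcome, predictors, treated,
                                     policy_year, ...)
        list(effect = fit$effect_size,
             auxiliary = list(weights = fit$donor_contributions,
                              pre_mspe = fit$pre_mspe))
      } else {
        keep <- panel$data$unit_id[panel$data$parent_state != ex]
        fit <- fit_did(panel_subset_units(panel, unique(keep)),
                       outcome, covariates, policy_year, ...)
        row <- fit$table[fit$table$term == "treated_post", ]
        list(effect = fit$effect_size,
             auxiliary = list(ci_low = row$ci_low, ci_high = row$ci_high,
                              p_value = row$p_value))
      }
    }, vaxpolicy_error = function(e) {
      list(effect = NA_real_, auxiliary = list(error = conditionMessage(e)))
    })
    rows[[i]] <- tibble::tibble(
      label = ex,
      effect_size = res$effect,
      failed = is.na(res$effect),
      auxiliary = list(res$auxiliary)
    )
  }
  structure(
    list(analysis = paste0(analysis, "_loo"), outcome = outcome,
         rows = dplyr::bind_rows(rows)),
    class = "sensitivity_table"
  )
}

#' Proxy-free subanalysis of the county DiD
#'
#' Refits the county difference-in-differences after dropping every county
#' belonging to a state whose overall coverage was proxy-substituted from
#' MMR coverage, so the estimate rests only on states reporting true overall
#' coverage.
#'
#' @param panel cleaned county-level `panel_dataset`.
#' @param report the [cleaning_report()] from [apply_county_filters()],
#'   identifying proxied counties.
#' @param covariates,policy_year,... passed to [fit_did()].
#' @param outcome outcome column (default `"overall"`).
#' @return a `did_result`.
#' @export
overall_only_subanalysis <- function(panel, report, covariates = character(),
                                     policy_year = panel$policy_year,
                                     outcome = "overall", ...) {
  validate_panel(panel)
  proxied_units <- unique(report$proxy_substitutions$unit_id)
  proxied_states <- unique(
    panel$data$parent_state[panel$data$unit_id %in% proxied_units])
  keep <- unique(panel$data$unit_id[
    !(panel$data$parent_state %in% proxied_states)])
  treated <- intersect(panel$treated_units, keep)
  control_states <- setdiff(
    unique(panel$data$parent_state[panel$data$unit_id %in% keep]),
    unique(panel$data$parent_state[
      panel$data$unit_id %in% panel$treated_units]))
  if (!length(treated) || !length(control_states)) {
    abort("no non-proxied treated or control states remain",
          "vaxpolicy_infeasible_error")
  }
  fit_did(panel_subset_units(panel, keep, treated_units = treated),
          outcome, covariates, policy_year, ...)
}

#' Predictor-combination sweep for the synthetic control
#'
#' Refits the synthetic control once per candidate predictor set to gauge
#' how the effect size depends on the covariates entering the match.
#'
#' @inheritParams fit_synthetic_control
#' @param predictor_sets list of character vectors of covariate names.
#' @return a `sensitivity_table`; `auxiliary` carries `pre_mspe`.
#' @export
covariate_sweep <- function(panel, outcome, predictor_sets, treated,
                            policy_year = panel$policy_year, ...) {
  if (!length(predictor_sets)) {
    abort("predictor_sets must be a nonempty list", "vaxpolicy_parameter_error")
  }
  rows <- vector("list", length(predictor_sets))
  for (i in seq_along(predictor_sets)) {
    set <- predictor_sets[[i]]
    label <- if (length(set)) paste(set, collapse = "+")
             else "(outcome mean only)"
    res <- tryCatch({
      fit <- fit_synthetic_control(panel, outcome, set, treated,
                                   policy_year, ...)
      list(effect = fit$effect_size,
           auxiliary = list(pre_mspe = fit$pre_mspe))
    }, vaxpolicy_error = function(e) {
      list(effect = NA_real_, auxiliary = list(error = conditionMessage(e)))
    })
    rows[[i]] <- tibble::tibble(
      label = label, effect_size = res$effect, failed = is.na(res$effect),
      auxiliary = list(res$auxiliary)
    )
  }
  structure(
    list(analysis = "covariate_sweep", outcome = outcome,
         rows = dplyr::bind_rows(rows)),
    class = "sensitivity_table"
  )
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat(sprintf("<sensitivity_table> %s, outcome '%s', %d rows (%d failed)\n",
              x$analysis, x$outcome, nrow(x$rows), sum(x$rows$failed)))
  rng <- range(x$rows$effect_size, na.rm = TRUE)
  cat(sprintf("  effect sizes span %.3f to %.3f pp\n", rng[1], rng[2]))
  invisible(x)
}
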