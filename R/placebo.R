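#' Rank a treated effect among placebo effects
#'
#' Orients all effect sizes so the hypothesized direction of the policy
#' effect is positive (e.g. a decrease in nonmedical exemptions counts
#' positively under `direction = "decrease"`), then ranks the treated effect
#' among the placebo effects. Ties count against the treated unit, the
#' conservative choice. The effect is classified as meaningful when the
#' treated unit falls in the top fifth percentile, the prespecified decision
#' rule.
#'
#' @param effects named numeric vector of placebo effect sizes (raw sign).
#' @param treated_effect the treated unit's effect size (raw sign).
#' @param direction hypothesized direction of the policy effect,
#'   `"increase"` or `"decrease"`.
#' @return list with `rank`, `n_evaluated`, `percentile` (100·rank/n) and
#'   `meaningful` (percentile <= 5).
#' @export
rank_and_classify <- function(effects, treated_effect,
                              direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (!length(effects)) {
    abort("effects must be nonempty", "vaxpolicy_parameter_error")
  }
  s <- if (direction == "increase") 1 else -1
  oriented <- s * effects
  oriented_treated <- s * treated_effect
  rank <- 1L + sum(oriented >= oriented_treated)
  n <- length(effects) + 1L
  pct <- 100 * rank / n
  list(rank = rank, n_evaluated = n, percentile = pct, meaningful = pct <= 5)
}

#' Placebo (permutation) tests for a synthetic-control effect
#'
#' Reassigns treatment status to each control unit in turn, refits the full
#' synthetic-control procedure with the same predictor set (the true treated
#' unit is removed from every placebo's donor pool, since it is exposed in
#' the post period), and compares the treated unit's effect size with the
#' distribution of placebo effects. Units whose placebo fit is infeasible
#' (e.g. missing data) are recorded as exclusions, not errors.
#'
#' @inheritParams fit_synthetic_control
#' @param direction hypothesized direction of the effect for this outcome.
#' @param sc_fit optional precomputed [fit_synthetic_control()] result for
#'   the treated unit; refitted when omitted.
#' @param mspe_ratio_cutoff optional numeric: when set, placebo units whose
#'   prepolicy MSPE exceeds `cutoff` times the treated unit's are dropped
#'   from the reference distribution. Off (`NULL`) by default: all feasible
#'   placebo fits are counted.
#' @return an object of class `placebo_result`.
#' @export
run_placebo_tests <- function(panel, outcome, predictors = character(),
                              treated, policy_year = panel$policy_year,
                              direction = c("increase", "decrease"),
                              sc_fit = NULL, mspe_ratio_cutoff = NULL,
                              outcome_lags = FALSE,
                              n_random_starts = 5L, seed = 20160701L) {
  direction <- match.arg(direction)
  if (is.null(sc_fit)) {
    sc_fit <- fit_synthetic_control(panel, outcome, predictors, treated,
                                    policy_year, outcome_lags,
                                    n_random_starts, seed)
  } else {
    outcome_lags <- sc_fit$outcome_lags %||% outcome_lags
  }
  # Placebo donor pool: the control units only. The true treated unit (and
  # any other unit carrying treatment) is exposed post-policy and would
  # contaminate the counterfactuals.
  controls <- setdiff(panel_units(panel), union(treated, panel$treated_units))

  effects <- numeric(0)
  pre_mspes <- numeric(0)
  excluded <- list()
  trajectories <- list()
  trajectories[[treated]] <- sc_fit$gaps
  for (u in controls) {
    fit <- tryCatch(
      fit_synthetic_control(
        panel_subset_units(panel, controls, treated_units = u),
        outcome, predictors, treated = u, policy_year = policy_year,
        outcome_lags = outcome_lags,
        n_random_starts = n_random_starts, seed = seed
      ),
      vaxpolicy_error = function(e) e
    )
    if (inherits(fit, "error")) {
      excluded[[u]] <- conditionMessage(fit)
      next
    }
    effects[u] <- fit$effect_size
    pre_mspes[u] <- fit$pre_mspe
    trajectories[[u]] <- fit$gaps
  }
  if (!is.null(mspe_ratio_cutoff)) {
    poor <- names(effects)[pre_mspes > mspe_ratio_cutoff * sc_fit$pre_mspe]
    for (u in poor) excluded[[u]] <- "pre_mspe_ratio_above_cutoff"
    effects <- effects[setdiff(names(effects), poor)]
  }
  if (!length(effects)) {
    abort("no feasible placebo fits", "vaxpolicy_infeasible_error")
  }
  cls <- rank_and_classify(effects, sc_fit$effect_size, direction)
  structure(
    list(
      outcome = outcome,
      treated_id = treated,
      direction = direction,
      treated_effect = sc_fit$effect_size,
      effects = effects,
      rank = cls$rank,
      n_evaluated = cls$n_evaluated,
      percentile = cls$percentile,
      meaningful = cls$meaningful,
      excluded_units = tibble::tibble(
        unit_id = names(excluded),
        reason = if (length(excluded)) unlist(excluded, use.names = FALSE)
                 else character(0)
      ),
      gap_trajectories = trajectories
    ),
    class = "placebo_result"
  )
}

#' @export
print.placebo_result <- function(x, ...) {
  cat(sprintf(
    "<placebo_result> outcome '%s' (%s): treated effect %+.3f pp, rank %d of %d (top %.1f%%) -> %smeaningful\n",
    x$outcome, x$direction, x$treated_effect, x$rank, x$n_evaluated,
    x$percentile, if (x$meaningful) "" else "not "
  ))
  invisible(x)
}
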