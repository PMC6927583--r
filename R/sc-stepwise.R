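#' Stepwise predictor selection with prepolicy cross-validation
#'
#' Chooses which covariates enter the synthetic-control predictor block by
#' forward stepwise selection validated on held-out prepolicy years: the
#' synthetic control is calibrated on the prepolicy years excluding the last
#' `holdout_years`, and a candidate set is scored by the mean squared gap on
#' those held-out years. Starting from the base set (the prepolicy outcome
#' mean, which is always included), the candidate that most reduces the
#' validation MSPE is added greedily; selection stops when no candidate
#' improves it by more than `min_improvement`. Ties break toward the earlier
#' candidate in `candidates`.
#'
#' @inheritParams build_sc_problem
#' @param candidates covariate names to consider.
#' @param holdout_years number of trailing prepolicy years held out for
#'   validation (default 1); must be smaller than the prepolicy span minus 1.
#' @param min_improvement minimum validation-MSPE reduction to accept a
#'   candidate.
#' @param n_random_starts,seed passed to [optimize_v()].
#' @return character vector of selected covariate names (empty when no
#'   candidate helps: matching then uses the prepolicy outcome mean only).
#' @export
select_predictors_stepwise <- function(panel, outcome, candidates, treated,
                                       policy_year = panel$policy_year,
                                       holdout_years = 1L,
                                       min_improvement = 1e-6,
                                       n_random_starts = 5L,
                                       seed = 20160701L) {
  validate_panel(panel)
  years <- panel_years(panel)
  pre_years <- years[years < policy_year]
  if (holdout_years < 1L || holdout_years >= length(pre_years) - 1L) {
    abort(sprintf(
      "holdout_years must lie in [1, %d] for a %d-year prepolicy span",
      length(pre_years) - 2L, length(pre_years)
    ), "vaxpolicy_parameter_error")
  }
  if (!length(candidates)) return(character(0))

  # Truncate the panel to the prepolicy span and recast the last
  # `holdout_years` of it as a pseudo post period.
  train_panel <- panel
  train_panel$data <- panel$data[panel$data$year < policy_year, , drop = FALSE]
  split_year <- pre_years[length(pre_years) - holdout_years + 1L]
  train_panel$policy_year <- as.integer(split_year)
  validate_panel(train_panel)

  val_mspe <- function(preds) {
    fit <- fit_synthetic_control(train_panel, outcome, preds, treated,
                                 policy_year = split_year,
                                 n_random_starts = n_random_starts,
                                 seed = seed)
    holdout <- as.integer(names(fit$gaps)) >= split_year
    mean(fit$gaps[holdout]^2)
  }

  selected <- character(0)
  current <- val_mspe(selected)
  remaining <- candidates
  while (length(remaining)) {
    scores <- vapply(remaining,
                     function(cd) val_mspe(c(selected, cd)), numeric(1))
    best <- which.min(scores)  # first index wins ties
    if (current - scores[best] > min_improvement) {
      selected <- c(selected, remaining[best])
      current <- scores[best]
      remaining <- remaining[-best]
    } else {
      break
    }
  }
  selected
}
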