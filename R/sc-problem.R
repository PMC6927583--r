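#' Assemble a synthetic-control problem
#'
#' Builds the matrices of the nested synthetic-control optimization for one
#' treated unit and one outcome: `X1`/`X0` hold the predictor values (the
#' prepolicy outcome mean plus each requested covariate averaged over the
#' prepolicy window, z-scored across treated + donors), `Z1`/`Z0` the
#' prepolicy outcome paths, and `Y1`/`Y0` the full outcome paths used for the
#' post-fit gaps. Donor units missing any predictor or any year of the
#' outcome are excluded and recorded; zero-variance predictor rows are
#' dropped.
#'
#' @param panel a `panel_dataset`.
#' @param outcome outcome column to model.
#' @param predictors character vector of covariate names entering the
#'   predictor block (may be empty: matching then uses only the prepolicy
#'   outcome mean).
#' @param treated id of the treated unit.
#' @param policy_year first post-policy year; defaults to the panel's.
#' @param outcome_lags when `TRUE`, the outcome enters the predictor block
#'   year by year (one row per prepolicy year) instead of as the prepolicy
#'   mean; this pins down the donor weights from the whole prepolicy path.
#' @return an object of class `sc_problem`.
#' @export
build_sc_problem <- function(panel, outcome, predictors = character(),
                             treated, policy_year = panel$policy_year,
                             outcome_lags = FALSE) {
  validate_panel(panel)
  if (!outcome %in% panel$outcomes) {
    abort(paste0("unknown outcome: ", outcome), "vaxpolicy_name_error")
  }
  d <- panel$data
  if (!treated %in% d$unit_id) {
    abort(paste0("treated unit not in panel: ", treated),
          "vaxpolicy_name_error")
  }
  years <- panel_years(panel)
  pre_years <- years[years < policy_year]
  post_years <- years[years >= policy_year]
  if (length(pre_years) < 2) {
    abort("at least 2 prepolicy years required", "vaxpolicy_history_error")
  }
  if (!length(post_years)) {
    abort("no postpolicy years in panel", "vaxpolicy_history_error")
  }
  if (length(predictors)) {
    if (is.null(panel$covariates)) {
      abort("panel carries no covariates but predictors were requested",
            "vaxpolicy_name_error")
    }
    bad <- setdiff(predictors, names(panel$covariates))
    if (length(bad)) {
      abort(paste0("unknown predictor(s): ", paste(bad, collapse = ", ")),
            "vaxpolicy_name_error")
    }
  }

  units <- panel_units(panel)
  # Every unit carrying (or exposed to) treatment is barred from the donor
  # pool, not only the unit under analysis.
  candidates <- setdiff(units, union(treated, panel$treated_units))

  path_of <- function(u, yrs) {
    rows <- d[d$unit_id == u & d$year %in% yrs, ]
    rows <- rows[order(rows$year), ]
    if (!identical(as.integer(rows$year), as.integer(yrs))) {
      return(rep(NA_real_, length(yrs)))
    }
    rows[[outcome]]
  }
  cov_pre_mean <- function(u) {
    if (!length(predictors)) return(numeric(0))
    rows <- panel$covariates[panel$covariates$unit_id == u &
                               panel$covariates$year %in% pre_years, ,
                             drop = FALSE]
    vapply(predictors, function(p) {
      v <- rows[[p]]
      if (is.null(v) || !length(v) || anyNA(v)) NA_real_ else mean(v)
    }, numeric(1))
  }

  y1 <- path_of(treated, years)
  z1 <- y1[years < policy_year]
  x1_cov <- cov_pre_mean(treated)
  if (anyNA(z1) || anyNA(x1_cov)) {
    abort("treated unit has missing prepolicy outcome or predictor data",
          "vaxpolicy_infeasible_error")
  }

  keep <- character(0)
  excluded <- list()
  Y0 <- NULL; X0_cov <- NULL
  for (u in candidates) {
    y <- path_of(u, years)
    xc <- cov_pre_mean(u)
    if (anyNA(y)) {
      excluded[[u]] <- "missing_outcome_data"
    } else if (anyNA(xc)) {
      excluded[[u]] <- "missing_predictor_data"
    } else {
      keep <- c(keep, u)
      Y0 <- cbind(Y0, y)
      X0_cov <- cbind(X0_cov, xc)
    }
  }
  if (length(keep) < 2) {
    abort(paste0(
      "fewer than 2 donors available after exclusions (",
      paste(sprintf("%s: %s", names(excluded), unlist(excluded)),
            collapse = "; "), ")"
    ), "vaxpolicy_infeasible_error")
  }
  colnames(Y0) <- keep
  Z0 <- Y0[years < policy_year, , drop = FALSE]

  # Predictor block: the prepolicy outcome (as its mean, or year by year when
  # outcome_lags is on) first, then covariate prepolicy means.
  if (outcome_lags) {
    out_names <- paste0("lag_", pre_years)
    X1_raw <- c(stats::setNames(z1, out_names), x1_cov)
    X0_raw <- rbind(Z0, if (length(predictors)) X0_cov)
  } else {
    out_names <- "outcome_pre_mean"
    X1_raw <- c(outcome_pre_mean = mean(z1), x1_cov)
    X0_raw <- rbind(colMeans(Z0),
                    if (length(predictors)) X0_cov)
  }
  rownames(X0_raw) <- names(X1_raw) <- c(out_names, predictors)

  ctr <- numeric(0); scl <- numeric(0)
  keep_rows <- logical(nrow(X0_raw))
  for (k in seq_len(nrow(X0_raw))) {
    all_vals <- c(X1_raw[k], X0_raw[k, ])
    m <- mean(all_vals); s <- stats::sd(all_vals)
    if (!is.finite(s) || s < 1e-12) next  # zero variance: drop predictor row
    keep_rows[k] <- TRUE
    ctr <- c(ctr, m); scl <- c(scl, s)
  }
  if (!any(keep_rows)) {
    abort("all predictor rows have zero variance across units",
          "vaxpolicy_infeasible_error")
  }
  pred_names <- rownames(X0_raw)[keep_rows]
  X1 <- (X1_raw[keep_rows] - ctr) / scl
  X0 <- sweep(sweep(X0_raw[keep_rows, , drop = FALSE], 1, ctr, "-"),
              1, scl, "/")
  names(ctr) <- names(scl) <- names(X1) <- rownames(X0) <- pred_names

  structure(
    list(
      treated_id = treated,
      donor_ids = keep,
      predictor_names = pred_names,
      X1 = X1, X0 = X0, Z1 = z1, Z0 = Z0,
      Y1_all = stats::setNames(y1, years),
      Y0_all = Y0,
      years = years, pre_years = pre_years, post_years = post_years,
      outcome = outcome, policy_year = as.integer(policy_year),
      scaling = list(center = ctr, scale = scl),
      excluded_donors = tibble::tibble(
        unit_id = names(excluded),
        reason = if (length(excluded)) unlist(excluded, use.names = FALSE)
                 else character(0)
      )
    ),
    class = "sc_problem"
  )
}

#' @export
print.sc_problem <- function(x, ...) {
  cat(sprintf(
    "<sc_problem> outcome '%s', treated %s, %d donors, %d predictors, %d pre / %d post years\n",
    x$outcome, x$treated_id, length(x$donor_ids), length(x$X1),
    length(x$pre_years), length(x$post_years)
  ))
  invisible(x)
}
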