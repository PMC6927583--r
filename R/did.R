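#' Build a difference-in-differences design
#'
#' Lays out the county-year regression for the 2x2 DiD specification:
#' intercept, treated indicator (counties of the treated state), post
#' indicator (year >= policy year), their interaction — the policy effect —
#' and any covariates, entered untransformed. Rows are clustered by county
#' for the sandwich covariance.
#'
#' @param panel a cleaned county-level `panel_dataset` (no missing cells for
#'   `outcome`).
#' @param outcome response column, in percentage points.
#' @param covariates covariate columns of `panel$covariates` to adjust for;
#'   must be observed for every county-year in the design.
#' @param policy_year first post-policy year.
#' @param year_fixed_effects when `TRUE`, replaces the single `post` column
#'   with year indicator columns (the interaction stays `treated x post`).
#' @return an object of class `did_design` with the response `y`, model
#'   matrix `X`, `cluster` ids and `column_names`.
#' @export
build_did_design <- function(panel, outcome, covariates = character(),
                             policy_year = panel$policy_year,
                             year_fixed_effects = FALSE) {
  validate_panel(panel)
  if (!outcome %in% panel$outcomes) {
    abort(paste0("unknown outcome: ", outcome), "vaxpolicy_name_error")
  }
  d <- panel$data[order(panel$data$unit_id, panel$data$year), , drop = FALSE]
  if (anyNA(d[[outcome]])) {
    i <- which(is.na(d[[outcome]]))[1]
    abort(sprintf("missing outcome cell at (%s, %d); clean the panel first",
                  d$unit_id[i], d$year[i]), "vaxpolicy_data_error")
  }
  treated <- as.numeric(d$unit_id %in% panel$treated_units)
  post <- as.numeric(d$year >= policy_year)
  X <- cbind(intercept = 1, treated = treated, post = post,
             treated_post = treated * post)
  if (year_fixed_effects) {
    yrs <- sort(unique(d$year))[-1]
    fe <- vapply(yrs, function(t) as.numeric(d$year == t),
                 numeric(nrow(d)))
    colnames(fe) <- paste0("year_", yrs)
    X <- cbind(X[, c("intercept", "treated", "treated_post"), drop = FALSE], fe)
  }
  if (length(covariates)) {
    if (is.null(panel$covariates)) {
      abort("panel carries no covariates", "vaxpolicy_name_error")
    }
    bad <- setdiff(covariates, names(panel$covariates))
    if (length(bad)) {
      abort(paste0("unknown covariate(s): ", paste(bad, collapse = ", ")),
            "vaxpolicy_name_error")
    }
    cv <- dplyr::left_join(d[c("unit_id", "year")], panel$covariates,
                           by = c("unit_id", "year"))
    for (cl in covariates) {
      if (anyNA(cv[[cl]])) {
        i <- which(is.na(cv[[cl]]))[1]
        abort(sprintf("missing covariate '%s' at (%s, %d)",
                      cl, d$unit_id[i], d$year[i]), "vaxpolicy_data_error")
      }
      X <- cbind(X, cv[[cl]])
      colnames(X)[ncol(X)] <- cl
    }
  }
  if (nrow(X) < ncol(X)) {
    abort("fewer observations than design columns", "vaxpolicy_data_error")
  }
  structure(
    list(
      y = d[[outcome]],
      X = X,
      cluster = d$unit_id,
      column_names = colnames(X),
      outcome = outcome,
      policy_year = as.integer(policy_year)
    ),
    class = "did_design"
  )
}

#' Ordinary least squares on a DiD design
#'
#' @param design a `did_design`.
#' @return list with named `coefficients`, `residuals` and `fitted`.
#' @export
fit_ols <- function(design) {
  stopifnot(inherits(design, "did_design"))
  X <- design$X
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- design$column_names[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(dep, collapse = ", ")), "vaxpolicy_collinearity_error")
  }
  beta <- qr.coef(qrX, design$y)
  fitted <- as.numeric(X %*% beta)
  list(
    coefficients = stats::setNames(as.numeric(beta), design$column_names),
    residuals = design$y - fitted,
    fitted = fitted
  )
}

#' Cluster-robust (CR1) sandwich covariance
#'
#' Computes the clustered sandwich covariance of the OLS coefficients,
#' (X'X)^-1 \[ sum_g X_g' e_g e_g' X_g \] (X'X)^-1, with the CR1 small-sample
#' factor G/(G-1) x (n-1)/(n-p). With every observation its own cluster this
#' reduces to the HC1 heteroskedasticity-robust covariance.
#'
#' @param design a `did_design`.
#' @param residuals OLS residuals from [fit_ols()].
#' @return the p x p covariance matrix.
#' @export
cluster_robust_covariance <- function(design, residuals) {
  stopifnot(inherits(design, "did_design"))
  X <- design$X
  n <- nrow(X)
  p <- ncol(X)
  cl <- design$cluster
  G <- length(unique(cl))
  if (G < 2) {
    abort("cluster-robust inference requires at least 2 clusters",
          "vaxpolicy_inference_error")
  }
  bread <- solve(crossprod(X))
  Xe <- X * residuals                      # row i: x_i * e_i
  # Score totals per cluster; meat = sum_g s_g s_g'.
  S <- rowsum(Xe, group = cl, reorder = FALSE)
  meat <- crossprod(S)
  adj <- (G / (G - 1)) * ((n - 1) / (n - p))
  V <- adj * bread %*% meat %*% bread
  dimnames(V) <- list(design$column_names, design$column_names)
  (V + t(V)) / 2
}

#' Difference-in-differences fit with cluster-robust inference
#'
#' Composes [build_did_design()], [fit_ols()] and
#' [cluster_robust_covariance()]. Confidence intervals and p-values use the t
#' distribution with `n_clusters - 1` degrees of freedom, the conservative
#' convention for clustered inference.
#'
#' @inheritParams build_did_design
#' @param conf_level confidence level (default 0.95).
#' @return an object of class `did_result`: coefficient table (estimate, se,
#'   CI bounds, p-value), covariance matrix, `n_obs` and `n_clusters`.
#' @export
fit_did <- function(panel, outcome, covariates = character(),
                    policy_year = panel$policy_year, conf_level = 0.95,
                    year_fixed_effects = FALSE) {
  design <- build_did_design(panel, outcome, covariates, policy_year,
                             year_fixed_effects)
  ols <- fit_ols(design)
  V <- cluster_robust_covariance(design, ols$residuals)
  G <- length(unique(design$cluster))
  se <- sqrt(pmax(diag(V), 0))
  df <- G - 1
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  est <- ols$coefficients
  tstat <- est / se
  table <- tibble::tibble(
    term = design$column_names,
    estimate = as.numeric(est),
    se = as.numeric(se),
    ci_low = as.numeric(est - tq * se),
    ci_high = as.numeric(est + tq * se),
    p_value = 2 * stats::pt(-abs(tstat), df)
  )
  structure(
    list(
      outcome = outcome,
      policy_year = design$policy_year,
      table = table,
      coefficients = est,
      covariance = V,
      effect_size = unname(est["treated_post"]),
      n_obs = nrow(design$X),
      n_clusters = G,
      df = df,
      conf_level = conf_level,
      residuals = ols$residuals
    ),
    class = "did_result"
  )
}

#' @export
print.did_result <- function(x, ...) {
  row <- x$table[x$table$term == "treated_post", ]
  cat(sprintf(
    "<did_result> outcome '%s': policy effect %+.2f pp (%.0f%% CI %.2f to %.2f, p = %.3g), %d county clusters, %d obs\n",
    x$outcome, row$estimate, 100 * x$conf_level, row$ci_low, row$ci_high,
    row$p_value, x$n_clusters, x$n_obs
  ))
  invisible(x)
}

#' Parallel-trends diagnostic
#'
#' Tabulates mean outcome by group (treated vs control) and year, and
#' compares the OLS time slopes fitted to the prepolicy group means. Under
#' parallel prepolicy trends the slope difference is near zero.
#'
#' @inheritParams build_did_design
#' @return list with `table` (group, year, mean, n, prepolicy flag) and
#'   `slope_difference` (treated slope minus control slope, pp/year).
#' @export
parallel_trends_check <- function(panel, outcome,
                                  policy_year = panel$policy_year) {
  validate_panel(panel)
  d <- panel$data
  grp <- ifelse(d$unit_id %in% panel$treated_units, "treated", "control")
  tab <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(group = grp, year = d$year,
                                   value = d[[outcome]]),
                    .data$group, .data$year),
    mean = mean(.data$value, na.rm = TRUE),
    n = sum(!is.na(.data$value)),
    .groups = "drop"
  )
  tab$prepolicy <- tab$year < policy_year
  pre <- tab[tab$prepolicy, ]
  if (length(unique(pre$year)) < 2) {
    abort("at least 2 prepolicy years required", "vaxpolicy_history_error")
  }
  slope <- function(g) {
    rows <- pre[pre$group == g, ]
    stats::coef(stats::lm(mean ~ year, data = rows))[["year"]]
  }
  list(table = tab, slope_difference = slope("treated") - slope("control"))
}
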