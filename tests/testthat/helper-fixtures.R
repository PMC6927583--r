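# Fixtures and independent oracles shared across the suite.

# Small deterministic state panel: outcomes supplied as a units x years
# matrix (list per outcome), optional covariates as a named list of
# per-unit vectors (constant over years).
make_state_panel <- function(outcomes, years, treated, policy_year,
                             covariates = NULL, level = "state",
                             parent_state = NULL, population = NULL) {
  units <- rownames(outcomes[[1]])
  grid <- expand.grid(year = years, unit_id = units,
                      stringsAsFactors = FALSE)[, 2:1]
  d <- tibble::tibble(
    unit_id = grid$unit_id,
    parent_state = if (is.null(parent_state)) grid$unit_id
                   else parent_state[grid$unit_id],
    year = as.integer(grid$year),
    population = if (is.null(population)) 1e6 else population[grid$unit_id]
  )
  for (oc in names(outcomes)) {
    d[[oc]] <- as.numeric(t(outcomes[[oc]]))
  }
  covs <- NULL
  if (!is.null(covariates)) {
    covs <- tibble::as_tibble(
      c(list(unit_id = units), lapply(covariates, as.numeric))
    )
    covs <- tidyr::crossing(covs, year = as.integer(years))
  }
  panel_dataset(d, level = level, treated_units = treated,
                policy_year = policy_year, covariates = covs)
}

# Grid-search oracle for the inner problem: minimize the V-weighted
# discrepancy over the simplex by exhaustive enumeration (J = 2 or 3),
# vectorized over the whole grid.
grid_inner_oracle <- function(X0, X1, V, step = 1e-3) {
  J <- ncol(X0)
  if (J == 2) {
    a <- seq(0, 1, step)
    W <- rbind(a, 1 - a)
  } else if (J == 3) {
    g <- expand.grid(a = seq(0, 1, step), b = seq(0, 1, step))
    g <- g[g$a + g$b <= 1 + 1e-12, ]
    W <- rbind(g$a, g$b, pmax(0, 1 - g$a - g$b))
  } else {
    stop("oracle supports J in {2, 3}")
  }
  R <- matrix(X1, length(X1), ncol(W)) - X0 %*% W
  objs <- colSums(V * R^2)
  i <- which.min(objs)
  list(objective = objs[i], w = W[, i])
}

# Brute-force cluster sandwich, written independently of the package:
# explicit loop over clusters, explicit matrix products.
brute_force_cluster_vcov <- function(X, e, cluster) {
  n <- nrow(X); p <- ncol(X)
  XtX_inv <- solve(t(X) %*% X)
  meat <- matrix(0, p, p)
  for (g in unique(cluster)) {
    idx <- which(cluster == g)
    Xg <- X[idx, , drop = FALSE]
    eg <- e[idx]
    sg <- t(Xg) %*% eg
    meat <- meat + sg %*% t(sg)
  }
  G <- length(unique(cluster))
  (G / (G - 1)) * ((n - 1) / (n - p)) * XtX_inv %*% meat %*% XtX_inv
}

# Tiny county panel with explicit cell values for the DiD arithmetic checks.
make_2x2_county_panel <- function(tr_pre = 90, tr_post = 94,
                                  co_pre = 91, co_post = 92) {
  d <- tibble::tibble(
    unit_id = c("CA_c1", "CA_c1", "S1_c1", "S1_c1"),
    parent_state = c("CA", "CA", "S1", "S1"),
    year = c(2015L, 2016L, 2015L, 2016L),
    population = 1e5,
    overall = c(tr_pre, tr_post, co_pre, co_post)
  )
  panel_dataset(d, level = "county", treated_units = "CA_c1",
                policy_year = 2016)
}
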