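# The inner donor-weight QP, the outer predictor-weight search, and the
# full synthetic-control fit.

toy_problem <- function(X0, X1, Z0 = NULL, Z1 = NULL) {
  J <- ncol(X0)
  donors <- paste0("d", seq_len(J))
  structure(list(
    treated_id = "tr", donor_ids = donors,
    predictor_names = paste0("p", seq_len(nrow(X0))),
    X1 = X1, X0 = `colnames<-`(X0, donors),
    Z1 = Z1 %||% X1, Z0 = Z0 %||% X0,
    years = seq_len(length(Z1 %||% X1)),
    pre_years = seq_len(length(Z1 %||% X1)), post_years = integer(0)
  ), class = "sc_problem")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("inner solver matches the hand-derivable instances", {
  # treated predictor equals donor 3 exactly: unit mass, zero objective
  X0 <- matrix(c(1, 5, 2, 7, 3, 9), 2, 3)
  pr <- toy_problem(X0, X1 = c(3, 9))
  sol <- solve_inner_weights(pr, c(1, 1))
  expect_equal(unname(sol$W), c(0, 0, 1), tolerance = 1e-8)
  expect_equal(sol$objective, 0, tolerance = 1e-12)

  # k = 1, X1 = 2 between donors (1, 4): interior optimum (2/3, 1/3)
  pr2 <- toy_problem(matrix(c(1, 4), 1, 2), X1 = 2)
  sol2 <- solve_inner_weights(pr2, 1)
  expect_equal(unname(sol2$W), c(2 / 3, 1 / 3), tolerance = 1e-8)
  expect_equal(sol2$objective, 0, tolerance = 1e-12)

  # k = 1, X1 = 5 beyond both donors (1, 2): corner solution at donor 2
  pr3 <- toy_problem(matrix(c(1, 2), 1, 2), X1 = 5)
  sol3 <- solve_inner_weights(pr3, 1)
  expect_equal(unname(sol3$W), c(0, 1), tolerance = 1e-8)
  expect_equal(sol3$objective, (5 - 2)^2, tolerance = 1e-8)
})

test_that("inner solver matches exhaustive grid search on random instances", {
  set.seed(914)
  for (i in 1:25) {
    k <- sample(1:2, 1)
    J <- sample(2:3, 1)
    X0 <- matrix(stats::rnorm(k * J, sd = 2), k, J)
    X1 <- stats::rnorm(k, sd = 2)
    V <- stats::runif(k)
    V <- V / sum(V)
    pr <- toy_problem(X0, X1)
    sol <- solve_inner_weights(pr, V)
    oracle <- grid_inner_oracle(X0, X1, V)
    expect_lte(sol$objective, oracle$objective + 1e-4)
    expect_gte(sol$objective, -1e-12)
  }
})

test_that("returned inner objective never exceeds any single-donor solution", {
  set.seed(2024)
  for (i in 1:20) {
    k <- sample(1:4, 1)
    J <- sample(2:12, 1)
    X0 <- matrix(stats::rnorm(k * J), k, J)
    X1 <- stats::rnorm(k)
    V <- stats::runif(k) + 0.01
    pr <- toy_problem(X0, X1)
    sol <- solve_inner_weights(pr, V)
    Vn <- V / sum(V)
    vertex_objs <- vapply(seq_len(J), function(j)
      sum(Vn * (X1 - X0[, j])^2), numeric(1))
    expect_lte(sol$objective, min(vertex_objs) + 1e-10)
    expect_equal(sum(sol$W), 1, tolerance = 1e-8)
    expect_true(all(sol$W >= -1e-10))
  }
})

test_that("inner solver validates predictor weights", {
  pr <- toy_problem(matrix(c(1, 4), 1, 2), X1 = 2)
  expect_error(solve_inner_weights(pr, c(-1, 1)),
               class = "vaxpolicy_parameter_error")
  expect_error(solve_inner_weights(pr, 0),
               class = "vaxpolicy_parameter_error")
})

hull_panel <- function(tau = 3, noise_sd = 0, seed = 77, n_states = 12) {
  sim_config(
    n_states = n_states, noise_sd = noise_sd, ar1_rho = 0,
    baseline = list(coverage = c(85, 3), nonmedical = c(6, 2),
                    medical = c(0.5, 0.3)),
    tau = c(coverage = tau, nonmedical = -3.9, medical = 2.4),
    treated_in_hull = TRUE, seed = seed
  )
}

test_that("problem construction excludes incomplete donors and standardizes predictors", {
  p <- simulate_state_panel(hull_panel())
  # punch a hole in one donor's outcome and one donor's covariate
  p$data$coverage[p$data$unit_id == "S03" & p$data$year == 2012] <- NA
  p$covariates$median_income[p$covariates$unit_id == "S04"] <- NA
  pr <- build_sc_problem(p, "coverage", c("median_income"), "CA")
  expect_false("S03" %in% pr$donor_ids)
  expect_false("S04" %in% pr$donor_ids)
  expect_setequal(pr$excluded_donors$unit_id, c("S03", "S04"))
  expect_setequal(pr$excluded_donors$reason,
                  c("missing_outcome_data", "missing_predictor_data"))
  # standardized rows: mean 0, sd 1 across treated + donors
  for (k in seq_len(nrow(pr$X0))) {
    vals <- c(pr$X1[k], pr$X0[k, ])
    expect_equal(mean(vals), 0, tolerance = 1e-12)
    expect_equal(sd(vals), 1, tolerance = 1e-12)
  }
})

test_that("empty predictor set and zero-variance predictors reduce k", {
  p <- simulate_state_panel(hull_panel())
  pr <- build_sc_problem(p, "coverage", character(), "CA")
  expect_equal(length(pr$X1), 1L)
  expect_equal(pr$predictor_names, "outcome_pre_mean")
  # constant covariate is dropped
  p$covariates$household_size <- 2.6
  pr2 <- build_sc_problem(p, "coverage",
                          c("household_size", "median_income"), "CA")
  expect_false("household_size" %in% pr2$predictor_names)
  expect_true("median_income" %in% pr2$predictor_names)
})

test_that("V optimization favors the informative predictor over pure noise", {
  p <- simulate_state_panel(hull_panel(noise_sd = 0.3, seed = 5))
  # noise covariate unrelated to outcomes
  set.seed(99)
  units <- unique(p$covariates$unit_id)
  noise <- stats::setNames(stats::rnorm(length(units), sd = 5), units)
  p$covariates$noise_cov <- noise[p$covariates$unit_id]
  pr <- build_sc_problem(p, "coverage", "noise_cov", "CA",
                         outcome_lags = FALSE)
  w <- optimize_v(pr)
  expect_gte(unname(w$V["outcome_pre_mean"]), 0.9)
  # exhaustive 101-point simplex grid is the oracle for k = 2
  grid_best <- min(vapply(seq(0, 1, length.out = 101), function(a)
    vaxpolicy:::sc_pre_mspe(pr, c(a, 1 - a)), numeric(1)))
  expect_lte(w$pre_mspe, grid_best + 1e-6)
})

test_that("optimize_v is deterministic and never worse than uniform V", {
  p <- simulate_state_panel(hull_panel(noise_sd = 0.5, seed = 9))
  pr <- build_sc_problem(p, "coverage",
                         c("median_income", "pct_white"), "CA",
                         outcome_lags = TRUE)
  w1 <- optimize_v(pr)
  w2 <- optimize_v(pr)
  expect_identical(w1$W, w2$W)
  expect_identical(w1$V, w2$V)
  k <- length(pr$X1)
  expect_lte(w1$pre_mspe, vaxpolicy:::sc_pre_mspe(pr, rep(1 / k, k)) + 1e-12)
  expect_equal(sum(w1$V), 1, tolerance = 1e-8)
  expect_equal(sum(w1$W), 1, tolerance = 1e-8)
})

test_that("noiseless in-hull panel is recovered exactly", {
  p <- simulate_state_panel(hull_panel(tau = 3, noise_sd = 0))
  fit <- fit_synthetic_control(p, "coverage", treated = "CA",
                               outcome_lags = TRUE)
  pre <- as.integer(names(fit$gaps)) < 2016
  expect_lt(max(abs(fit$gaps[pre])), 1e-6)
  expect_equal(fit$effect_size, 3, tolerance = 1e-6)
})

test_that("gaps satisfy their defining identity and common shifts cancel", {
  p <- simulate_state_panel(hull_panel(noise_sd = 0.5, seed = 21))
  fit <- fit_synthetic_control(p, "coverage", treated = "CA",
                               outcome_lags = TRUE)
  pr <- build_sc_problem(p, "coverage", character(), "CA",
                         outcome_lags = TRUE)
  # gap(t) = Y1(t) - sum_j W_j Y0_j(t), exactly
  manual <- as.numeric(pr$Y1_all) - as.numeric(pr$Y0_all %*% fit$donor_contributions)
  expect_equal(unname(fit$gaps), manual, tolerance = 1e-10)
  pre <- as.integer(names(fit$gaps)) < 2016
  expect_equal(fit$effect_size,
               mean(fit$gaps[!pre]) - mean(fit$gaps[pre]),
               tolerance = 1e-10)

  # add a common +10 to every outcome value of every unit: gaps unchanged
  # (panel centered at 50 so the shift stays inside the [0, 100] bounds)
  plow <- simulate_state_panel(sim_config(
    n_states = 12, noise_sd = 0.5, ar1_rho = 0,
    baseline = list(coverage = c(50, 3), nonmedical = c(6, 2),
                    medical = c(0.5, 0.3)),
    treated_in_hull = TRUE, seed = 21
  ))
  fitlow <- fit_synthetic_control(plow, "coverage", treated = "CA",
                                  outcome_lags = TRUE)
  p10 <- plow
  p10$data$coverage <- p10$data$coverage + 10
  fit10 <- fit_synthetic_control(p10, "coverage", treated = "CA",
                                 outcome_lags = TRUE)
  expect_equal(fit10$gaps, fitlow$gaps, tolerance = 1e-8)
  expect_equal(fit10$effect_size, fitlow$effect_size, tolerance = 1e-8)
})

test_that("infeasible problems raise informative errors", {
  p <- simulate_state_panel(hull_panel(n_states = 3))
  p$data$coverage[p$data$unit_id == "S01"] <- NA
  expect_error(build_sc_problem(p, "coverage", character(), "CA"),
               "fewer than 2 donors", class = "vaxpolicy_infeasible_error")
  p2 <- simulate_state_panel(hull_panel())
  expect_error(build_sc_problem(p2, "nope", character(), "CA"),
               class = "vaxpolicy_name_error")
  expect_error(
    build_sc_problem(p2, "coverage", character(), "CA", policy_year = 2012),
    class = "vaxpolicy_history_error"
  )
})
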