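# Nested synthetic-control optimization.
#
# Inner problem: donor weights W on the simplex minimizing the
# V-weighted predictor discrepancy (X1 - X0 W)' diag(V) (X1 - X0 W).
# Outer problem: predictor weights V on the simplex minimizing the mean
# squared prepolicy outcome discrepancy of W*(V).

# Quadratic minimization over the probability simplex in Gram form:
#   min w'G w - 2 c'w  s.t.  w >= 0, sum(w) = 1,
# where G = B'B and c = B'd for the least-squares problem min ||d - B w||^2.
# Active-set method: start at the best vertex, alternate between solving the
# equality-constrained problem on the current support (KKT system) and
# exchanging support members by the sign of the reduced gradient. Exact for
# these small problems (J <= ~50 donors) and fully deterministic.
simplex_qp <- function(G, c_, tol = 1e-12) {
  J <- ncol(G)
  if (J == 1L) return(1)
  eq_solve <- function(idx) {
    m <- length(idx)
    K <- rbind(cbind(2 * G[idx, idx, drop = FALSE], rep(1, m)),
               c(rep(1, m), 0))
    rhs <- c(2 * c_[idx], 1)
    sol <- tryCatch(solve(K, rhs),
                    error = function(e) as.numeric(MASS::ginv(K) %*% rhs))
    sol[seq_len(m)]
  }
  vertex_obj <- diag(G) - 2 * c_
  w <- numeric(J)
  w[which.min(vertex_obj)] <- 1
  P <- w > 0
  for (iter in seq_len(100L + 20L * J)) {
    idx <- which(P)
    wP <- eq_solve(idx)
    if (min(wP) >= -1e-10) {
      w[] <- 0
      w[idx] <- pmax(wP, 0)
      w <- w / sum(w)
      g <- as.numeric(2 * (G %*% w - c_))
      gmin_free <- min(g[P])
      cand <- which(!P)
      if (!length(cand)) break
      viol <- cand[g[cand] < gmin_free - 1e-9 * (1 + abs(gmin_free))]
      if (!length(viol)) break
      P[viol[which.min(g[viol])]] <- TRUE
    } else {
      # Step toward the unconstrained-on-support solution until the first
      # weight hits zero, then drop it from the support.
      cur <- w[idx]
      dirn <- wP - cur
      blocking <- which(wP < 0 & dirn < 0)
      alpha <- min(cur[blocking] / (cur[blocking] - wP[blocking]))
      cur <- cur + alpha * dirn
      cur[cur < tol] <- 0
      w[] <- 0
      w[idx] <- cur
      w <- w / sum(w)
      P <- w > 0
    }
  }
  w
}

# Least-squares convenience wrapper: min ||d - B w||^2 over the simplex.
simplex_lsq <- function(B, d) {
  B <- as.matrix(B)
  simplex_qp(crossprod(B), as.numeric(crossprod(B, d)))
}

#' Solve the inner donor-weight problem
#'
#' For fixed predictor weights `V`, finds the donor weights `W` on the
#' simplex (nonnegative, summing to one) that minimize the V-weighted
#' squared predictor discrepancy between the treated unit and the weighted
#' donors. Deterministic for fixed inputs.
#'
#' @param problem an `sc_problem` from [build_sc_problem()].
#' @param V nonnegative predictor weights (length k, not all zero); they are
#'   normalized to sum to one.
#' @return list with `W` (named donor weights) and `objective` (the attained
#'   weighted discrepancy).
#' @export
solve_inner_weights <- function(problem, V) {
  stopifnot(inherits(problem, "sc_problem"))
  k <- length(problem$X1)
  if (length(V) != k || any(V < 0) || all(V == 0) || anyNA(V)) {
    abort("V must be nonnegative, not all zero, of length k",
          "vaxpolicy_parameter_error")
  }
  V <- V / sum(V)
  X0 <- problem$X0
  G <- crossprod(X0 * sqrt(V))              # X0' diag(V) X0
  c_ <- as.numeric(crossprod(X0, V * problem$X1))
  w <- simplex_qp(G, c_)
  r <- problem$X1 - as.numeric(X0 %*% w)
  obj <- sum(V * r^2)
  if (!is.finite(obj)) {
    abort(sprintf("inner solver failed (residual norm %g)", sqrt(sum(r^2))),
          "vaxpolicy_optim_error")
  }
  list(W = stats::setNames(as.numeric(w), problem$donor_ids), objective = obj)
}

inner_weights_fast <- function(problem, V) {
  V <- V / sum(V)
  X0 <- problem$X0
  G <- crossprod(X0 * sqrt(V))
  c_ <- as.numeric(crossprod(X0, V * problem$X1))
  simplex_qp(G, c_)
}

# Mean squared prepolicy outcome discrepancy at predictor weights V.
sc_pre_mspe <- function(problem, V) {
  w <- inner_weights_fast(problem, V)
  mean((problem$Z1 - as.numeric(problem$Z0 %*% w))^2)
}

softmax <- function(theta) {
  e <- exp(theta - max(theta))
  e / sum(e)
}

#' Optimize predictor weights
#'
#' Chooses predictor weights `V` on the simplex to minimize the mean squared
#' prepolicy outcome discrepancy of the induced donor weights, by a
#' deterministic multi-start derivative-free search (Nelder-Mead on the
#' softmax-parameterized simplex; starts at the uniform vector, each simplex
#' vertex, and a fixed-seed random sample). The returned `V` is never worse
#' than the uniform weighting.
#'
#' @param problem an `sc_problem`.
#' @param n_random_starts number of additional random starts (default 5).
#' @param seed seed for the random starts; fixed so repeated calls are
#'   bit-identical.
#' @return an object of class `sc_weights`: donor weights `W`, predictor
#'   weights `V`, the attained inner objective and `pre_mspe`.
#' @export
optimize_v <- function(problem, n_random_starts = 5L, seed = 20160701L) {
  stopifnot(inherits(problem, "sc_problem"))
  if (length(problem$Z1) < 2) {
    abort("at least 2 prepolicy years required to calibrate V",
          "vaxpolicy_history_error")
  }
  k <- length(problem$X1)
  cand_V <- list(rep(1 / k, k))
  if (k > 1) {
    for (j in seq_len(k)) cand_V[[length(cand_V) + 1]] <- as.numeric(j == seq_len(k))
    f <- function(theta) sc_pre_mspe(problem, softmax(c(0, theta)))
    starts <- list(rep(0, k - 1))
    if (sc_pre_mspe(problem, rep(1 / k, k)) < 1e-14) starts <- list()
    for (j in seq_len(k)) {
      th <- rep(0, k - 1)
      if (j == 1) th[] <- -12 else th[j - 1] <- 12
      starts[[length(starts) + 1]] <- th
    }
    rand <- with_local_seed(seed,
      matrix(stats::rnorm(n_random_starts * (k - 1), sd = 2),
             nrow = n_random_starts))
    for (i in seq_len(nrow(rand))) starts[[length(starts) + 1]] <- rand[i, ]
    for (th0 in starts) {
      th_opt <- if (k == 2) {
        stats::optimize(function(t) f(t), interval = th0[1] + c(-15, 15),
                        tol = 1e-9)$minimum
      } else {
        suppressWarnings(stats::optim(
          th0, f, method = "Nelder-Mead",
          control = list(maxit = 300, reltol = 1e-9)
        )$par)
      }
      cand_V[[length(cand_V) + 1]] <- softmax(c(0, th_opt))
    }
  }
  best_V <- NULL
  best_mspe <- Inf
  for (V in cand_V) {
    m <- sc_pre_mspe(problem, V)
    if (m < best_mspe - 1e-15) {
      best_mspe <- m
      best_V <- V
    }
  }
  inner <- solve_inner_weights(problem, best_V)
  structure(
    list(
      W = inner$W,
      V = stats::setNames(best_V, problem$predictor_names),
      inner_objective = inner$objective,
      pre_mspe = best_mspe
    ),
    class = "sc_weights"
  )
}

#' @export
print.sc_weights <- function(x, ...) {
  nz <- x$W[x$W > 1e-4]
  cat(sprintf("<sc_weights> pre-MSPE %.4g; %d donor(s) with weight > 1e-4:\n",
              x$pre_mspe, length(nz)))
  print(round(sort(nz, decreasing = TRUE), 4))
  invisible(x)
}

#' Fit a synthetic control
#'
#' Full pipeline for one treated unit and one outcome: assemble the problem
#' ([build_sc_problem()]), calibrate predictor and donor weights
#' ([optimize_v()]), and compute the per-year gap between the treated unit
#' and its synthetic control plus the pre-to-post effect size
#' (mean postpolicy gap minus mean prepolicy gap, in percentage points).
#'
#' @inheritParams build_sc_problem
#' @param n_random_starts,seed passed to [optimize_v()].
#' @return an object of class `sc_result`.
#' @export
fit_synthetic_control <- function(panel, outcome, predictors = character(),
                                  treated, policy_year = panel$policy_year,
                                  outcome_lags = FALSE,
                                  n_random_starts = 5L, seed = 20160701L) {
  problem <- build_sc_problem(panel, outcome, predictors, treated, policy_year,
                              outcome_lags = outcome_lags)
  weights <- optimize_v(problem, n_random_starts = n_random_starts, seed = seed)
  synth <- as.numeric(problem$Y0_all %*% weights$W)
  gaps <- stats::setNames(as.numeric(problem$Y1_all) - synth, problem$years)
  pre <- problem$years < policy_year
  effect <- mean(gaps[!pre]) - mean(gaps[pre])
  structure(
    list(
      treated_id = problem$treated_id,
      outcome = outcome,
      policy_year = problem$policy_year,
      weights = weights,
      donor_contributions = weights$W,
      gaps = gaps,
      synthetic_path = stats::setNames(synth, problem$years),
      treated_path = problem$Y1_all,
      effect_size = effect,
      pre_mspe = weights$pre_mspe,
      predictors = predictors,
      outcome_lags = outcome_lags,
      excluded_donors = problem$excluded_donors
    ),
    class = "sc_result"
  )
}

#' @export
print.sc_result <- function(x, ...) {
  cat(sprintf(
    "<sc_result> outcome '%s', treated %s: effect size %+.3f pp (pre-MSPE %.4g)\n",
    x$outcome, x$treated_id, x$effect_size, x$pre_mspe
  ))
  invisible(x)
}
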