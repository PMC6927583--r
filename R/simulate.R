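#' Simulation configuration for synthetic vaccination panels
#'
#' Parameterizes the data-generating process used for parameter-recovery
#' testing of both analyses. Outcomes follow an interactive factor model:
#' unit effect + year effect (common trend plus shocks) + latent-factor term
#' + injected treated-x-post policy effect + AR(1) noise, clamped to
#' \[0, 100\] percentage points. Defaults mirror the study setting: 45 states
#' observed 2011-2017 with the policy taking effect in the 2016 school year;
#' 2015-style baselines (coverage 94.2 pp, nonmedical exemptions 2.2 pp,
#' medical exemptions 0.3 pp) and policy effects with the observed sign
#' structure (coverage up, nonmedical exemptions down, medical exemptions
#' up).
#'
#' @param n_states number of states (including the treated one).
#' @param counties_per_state integer range `c(min, max)` of counties drawn
#'   per state in county panels.
#' @param treated_counties optional fixed number of counties for the treated
#'   state (e.g. 57 for a California-sized panel); `NULL` draws it like any
#'   other state.
#' @param years inclusive school-year range of the panel.
#' @param policy_year first post-policy school year (interior to `years`).
#' @param treated_state id of the treated state.
#' @param baseline named list: outcome -> c(mean, between-unit sd), pp.
#' @param common_trend common linear drift, pp per year.
#' @param year_shock_sd sd of common year shocks, pp.
#' @param n_factors number of latent factors.
#' @param factor_scale sd of factor loadings relative to the between-unit sd.
#' @param noise_sd sd of the AR(1) innovation noise, pp; either one value
#'   for all outcomes or a named vector with one entry per outcome
#'   (exemption series are an order of magnitude smaller than coverage and
#'   correspondingly less noisy).
#' @param ar1_rho AR(1) autocorrelation of the noise in \[-1, 1\].
#' @param tau named vector: outcome -> injected treated-x-post effect, pp.
#' @param county_icc intraclass correlation of county outcomes within states.
#' @param effect_heterogeneity county-level effect modifier: the injected
#'   effect scales with the unit's room to move (lower prepolicy coverage ->
#'   larger coverage gain; higher prepolicy exemptions -> larger decline),
#'   with this coefficient per between-county sd. 0 disables it.
#' @param missing_rate probability that an outcome cell is set missing by
#'   [inject_missingness()].
#' @param treated_in_hull when `TRUE`, the treated state's unit effects and
#'   factor loadings are a convex combination of three donors', so a synthetic
#'   control with the right weights exists exactly and the estimator's
#'   identifying assumption holds by construction; when `FALSE` the treated
#'   unit is drawn like any other and may lie outside the donor hull.
#' @param seed integer seed; the generators are bit-reproducible given it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_states = 45L,
                       counties_per_state = c(4L, 12L),
                       treated_counties = NULL,
                       years = 2011:2017,
                       policy_year = 2016L,
                       treated_state = "CA",
                       baseline = list(coverage = c(94.2, 2.5),
                                       nonmedical = c(2.2, 1.3),
                                       medical = c(0.3, 0.2)),
                       common_trend = 0.1,
                       year_shock_sd = 0.2,
                       n_factors = 2L,
                       factor_scale = 0.5,
                       noise_sd = 0.5,
                       ar1_rho = 0.5,
                       tau = c(coverage = 4.3, nonmedical = -3.9,
                               medical = 2.4),
                       county_icc = 0.3,
                       effect_heterogeneity = 0.5,
                       missing_rate = 0,
                       treated_in_hull = FALSE,
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(n_states >= 3, "n_states must be >= 3")
  chk(length(years) >= 4, "years must span at least 4 school years")
  chk(policy_year > min(years) && policy_year <= max(years),
      "policy_year must be interior to years")
  chk(all(counties_per_state >= 1) && length(counties_per_state) == 2 &&
        counties_per_state[1] <= counties_per_state[2],
      "counties_per_state must be an increasing pair of positive integers")
  chk(abs(ar1_rho) <= 1, "ar1_rho must lie in [-1, 1]")
  chk(county_icc >= 0 && county_icc < 1, "county_icc must lie in [0, 1)")
  chk(missing_rate >= 0 && missing_rate < 1, "missing_rate must lie in [0, 1)")
  chk(all(noise_sd >= 0), "noise_sd must be nonnegative")
  chk(length(noise_sd) == 1 || all(names(baseline) %in% names(noise_sd)),
      "noise_sd must be scalar or named per outcome")
  chk(all(names(tau) %in% names(baseline)),
      "every tau outcome needs a baseline entry")
  for (oc in names(baseline)) {
    b <- baseline[[oc]]
    chk(length(b) == 2 && b[2] >= 0 && b[1] >= 0 && b[1] <= 100,
        sprintf("baseline for '%s' must be c(mean in [0,100], sd >= 0)", oc))
  }
  if (length(problems)) {
    abort(paste0("invalid simulation config: ",
                 paste(problems, collapse = "; ")),
          "vaxpolicy_parameter_error")
  }
  cfg
}

# AR(1) noise path of length T with innovation sd `sd`, stationary start.
ar1_noise <- function(T, rho, sd) {
  if (sd == 0) return(numeric(T))
  e <- stats::rnorm(T, sd = sd)
  x <- numeric(T)
  x[1] <- if (abs(rho) < 1) e[1] / sqrt(1 - rho^2) else e[1]
  for (t in seq_len(T)[-1]) x[t] <- rho * x[t - 1] + e[t]
  x
}

# Covariate names shared by both generators (Table-1-style county
# characteristics; a subset doubles as SC predictor candidates).
sim_covariate_names <- function() {
  c("median_income", "household_size", "population_100k", "poverty",
    "pct_white", "educ_less_hs", "educ_some_college", "educ_bachelor",
    "uninsured_children")
}

noise_sd_for <- function(cfg, oc) {
  if (length(cfg$noise_sd) > 1) unname(cfg$noise_sd[[oc]]) else cfg$noise_sd
}

# Shared machinery: outcomes for a set of units given unit effects.
# unit_effects: named list outcome -> numeric vector (one per unit).
sim_outcome_matrix <- function(cfg, units, unit_effects, treated_units,
                               effect_scale = NULL, hull = NULL) {
  years <- cfg$years
  T <- length(years)
  out <- list()
  for (oc in names(cfg$baseline)) {
    mu <- cfg$baseline[[oc]][1]
    sd_u <- cfg$baseline[[oc]][2]
    delta <- cfg$common_trend * (years - years[1]) +
      stats::rnorm(T, sd = cfg$year_shock_sd)
    f <- matrix(stats::rnorm(cfg$n_factors * T), cfg$n_factors, T)
    lambda <- matrix(stats::rnorm(length(units) * cfg$n_factors,
                                  sd = cfg$factor_scale * sd_u),
                     length(units), cfg$n_factors)
    if (!is.null(hull)) {
      lambda[1, ] <- as.numeric(hull$w %*% lambda[hull$idx, , drop = FALSE])
    }
    tau_oc <- if (oc %in% names(cfg$tau)) cfg$tau[[oc]] else 0
    m <- matrix(0, length(units), T, dimnames = list(units, years))
    for (i in seq_along(units)) {
      eff <- tau_oc
      if (!is.null(effect_scale)) eff <- tau_oc * effect_scale[[oc]][i]
      y <- mu + unit_effects[[oc]][i] + delta +
        as.numeric(lambda[i, ] %*% f) +
        ar1_noise(T, cfg$ar1_rho, noise_sd_for(cfg, oc)) +
        eff * (units[i] %in% treated_units) * (years >= cfg$policy_year)
      m[i, ] <- pmin(100, pmax(0, y))
    }
    out[[oc]] <- m
  }
  out
}

# Unit covariates correlated with the coverage unit effect so predictor
# selection has signal; constant over years.
sim_covariates <- function(cfg, units, alpha_cov, years) {
  sd_u <- cfg$baseline[["coverage"]][2]
  a <- alpha_cov / max(sd_u, 1e-8)   # standardized unit effect
  n <- length(units)
  cov_unit <- tibble::tibble(
    unit_id = units,
    median_income = 6 + 0.8 * a + stats::rnorm(n, sd = 0.5),
    household_size = 2.6 + stats::rnorm(n, sd = 0.2),
    population_100k = exp(stats::rnorm(n, mean = 0.5, sd = 0.8)),
    poverty = pmax(0, 14 - 2 * a + stats::rnorm(n, sd = 2)),
    pct_white = pmin(100, pmax(0, 70 + 5 * a + stats::rnorm(n, sd = 8))),
    educ_less_hs = pmax(0, 12 - 1.5 * a + stats::rnorm(n, sd = 2)),
    educ_some_college = pmax(0, 28 + stats::rnorm(n, sd = 3)),
    educ_bachelor = pmax(0, 30 + 2 * a + stats::rnorm(n, sd = 4)),
    uninsured_children = pmax(0, 6 - a + stats::rnorm(n, sd = 1.5))
  )
  tidyr::crossing(cov_unit, year = years)
}

outcome_list_to_tibble <- function(outcomes, units, years, parent_state,
                                   population) {
  base <- tidyr::crossing(unit_id = units, year = years)
  base <- base[order(match(base$unit_id, units), base$year), ]
  d <- tibble::tibble(
    unit_id = base$unit_id,
    parent_state = parent_state[base$unit_id],
    year = as.integer(base$year),
    population = population[base$unit_id]
  )
  for (oc in names(outcomes)) {
    d[[oc]] <- as.numeric(t(outcomes[[oc]]))  # unit-major, year within unit
  }
  d
}

#' Simulate a state-level vaccination panel
#'
#' Generates coverage and exemption outcomes for `n_states` states under the
#' factor-model process described in [sim_config()], with the policy effect
#' injected for the treated state from the policy year on. Covariates are
#' correlated with the coverage unit effects so that predictor selection has
#' signal. Bit-reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a `panel_dataset` at state level.
#' @export
simulate_state_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(derive_seed(cfg$seed, "state_panel"), {
    units <- c(cfg$treated_state,
               sprintf("S%02d", seq_len(cfg$n_states - 1)))
    unit_effects <- lapply(cfg$baseline, function(b)
      stats::rnorm(length(units), sd = b[2]))
    hull <- NULL
    if (isTRUE(cfg$treated_in_hull)) {
      m <- min(3L, length(units) - 1L)
      idx <- sample(2:length(units), m)
      w <- stats::runif(m)
      hull <- list(idx = idx, w = w / sum(w))
      for (oc in names(unit_effects)) {
        unit_effects[[oc]][1] <- sum(hull$w * unit_effects[[oc]][hull$idx])
      }
    }
    outcomes <- sim_outcome_matrix(cfg, units, unit_effects,
                                   cfg$treated_state, hull = hull)
    population <- stats::setNames(
      round(exp(stats::rnorm(length(units), mean = 14.8, sd = 1))), units)
    covs <- sim_covariates(cfg, units, unit_effects[["coverage"]], cfg$years)
    d <- outcome_list_to_tibble(outcomes, units, cfg$years,
                                stats::setNames(units, units), population)
    panel_dataset(d, level = "state", treated_units = cfg$treated_state,
                  policy_year = cfg$policy_year, covariates = covs,
                  outcomes = names(cfg$baseline))
  })
}

#' Simulate a county-level vaccination panel
#'
#' Counties are nested in states and inherit a state-level random effect
#' calibrated so the intraclass correlation of outcomes within states equals
#' `county_icc`. County populations are drawn log-normally so the 65,000
#' inclusion filter binds. Counties of the treated state receive the injected
#' effect; with `effect_heterogeneity > 0` the effect is larger where there
#' is more room to move (lower prepolicy coverage, higher prepolicy
#' exemptions), emulating the observed hot-spot pattern. The panel reports
#' both `overall` coverage and `mmr` (highly correlated), so the
#' MMR-as-proxy rule can be exercised.
#'
#' @param cfg a [sim_config()].
#' @return a `panel_dataset` at county level; the treated units are the
#'   treated state's counties.
#' @export
simulate_county_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(derive_seed(cfg$seed, "county_panel"), {
    states <- c(cfg$treated_state,
                sprintf("S%02d", seq_len(cfg$n_states - 1)))
    rng <- cfg$counties_per_state
    n_cty <- stats::setNames(
      if (rng[1] == rng[2]) rep(rng[1], length(states))
      else sample(seq(rng[1], rng[2]), length(states), replace = TRUE),
      states)
    if (!is.null(cfg$treated_counties)) {
      n_cty[cfg$treated_state] <- as.integer(cfg$treated_counties)
    }
    units <- unlist(lapply(states, function(s)
      sprintf("%s_c%02d", s, seq_len(n_cty[s]))))
    parent <- stats::setNames(rep(states, n_cty[states]), units)

    # Split the between-unit variance into state and county components so
    # that var(state) / (var(state) + var(county) + var(noise)) = county_icc.
    unit_effects <- list()
    for (oc in names(cfg$baseline)) {
      sd_u <- cfg$baseline[[oc]][2]
      tot <- sd_u^2 + noise_sd_for(cfg, oc)^2
      v_state <- cfg$county_icc * tot
      v_county <- max(sd_u^2 - v_state, 1e-12)
      u_s <- stats::setNames(stats::rnorm(length(states),
                                          sd = sqrt(v_state)), states)
      unit_effects[[oc]] <- u_s[parent[units]] +
        stats::rnorm(length(units), sd = sqrt(v_county))
    }

    # Effect modifier: deviation of the unit's systematic level from the
    # grand mean, oriented so that "more room to move" means a larger effect.
    effect_scale <- NULL
    if (cfg$effect_heterogeneity > 0) {
      effect_scale <- list()
      for (oc in names(cfg$baseline)) {
        dev <- unit_effects[[oc]] / max(stats::sd(unit_effects[[oc]]), 1e-8)
        s <- if (oc %in% names(cfg$tau) && cfg$tau[[oc]] < 0) 1 else -1
        effect_scale[[oc]] <- pmax(0, 1 + cfg$effect_heterogeneity * s * dev)
      }
    }

    outcomes <- sim_outcome_matrix(cfg, units, unit_effects,
                                   units[parent[units] == cfg$treated_state],
                                   effect_scale)
    # MMR coverage: overall coverage plus a small independent wobble.
    outcomes$mmr <- pmin(100, pmax(0, outcomes$coverage +
      matrix(stats::rnorm(length(outcomes$coverage), sd = 0.3),
             nrow(outcomes$coverage))))
    names(outcomes)[names(outcomes) == "coverage"] <- "overall"

    population <- stats::setNames(
      round(exp(stats::rnorm(length(units), mean = 11, sd = 1))), units)
    covs <- sim_covariates(cfg, units, unit_effects[["coverage"]], cfg$years)
    d <- outcome_list_to_tibble(outcomes, units, cfg$years, parent,
                                population)
    panel_dataset(d, level = "county",
                  treated_units = units[parent[units] == cfg$treated_state],
                  policy_year = cfg$policy_year, covariates = covs,
                  outcomes = c("overall", "mmr",
                               setdiff(names(cfg$baseline), "coverage")))
  })
}

#' Inject missingness into a panel
#'
#' Sets each outcome cell missing independently with probability
#' `missing_rate`, reproducibly from `seed`. Used to exercise the
#' impute-or-exclude cleaning logic.
#'
#' @param panel a `panel_dataset`.
#' @param missing_rate probability in \[0, 1).
#' @param seed integer seed for the mask.
#' @return the panel with missing cells.
#' @export
inject_missingness <- function(panel, missing_rate, seed = 1L) {
  validate_panel(panel)
  if (!is_scalar_number(missing_rate) || missing_rate < 0 ||
      missing_rate >= 1) {
    abort("missing_rate must lie in [0, 1)", "vaxpolicy_parameter_error")
  }
  if (missing_rate == 0) return(panel)
  with_local_seed(seed, {
    for (oc in panel$outcomes) {
      mask <- stats::runif(nrow(panel$data)) < missing_rate
      panel$data[[oc]][mask] <- NA_real_
    }
  })
  panel
}
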