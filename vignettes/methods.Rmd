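---
title: "Methods: synthetic control and clustered DiD for school-vaccination policy evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic control and clustered DiD for school-vaccination policy evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical machinery of `vaxpolicy`: the models,
the estimators, the numerical choices, the design decisions taken where the
problem was genuinely open, and what the test suite does and does not
establish about behaviour on real data.

## The evaluation problem

A single state changes its school-entry vaccination law (the motivating case
is California's 2016 elimination of nonmedical exemptions, effective with the
2016–2017 school year; years throughout are school-year starts, so 2016
means 2016–2017). Outcomes are percentages of kindergarten entrants — vaccine
coverage, nonmedical exemption (NME) prevalence, medical exemption (ME)
prevalence — observed annually for many states (or counties nested in
states). Two complementary designs estimate the policy effect in percentage
points:

* a **synthetic control** at the state level, where only one treated unit
  exists and a weighted combination of donor states serves as its
  counterfactual; and
* a **difference-in-differences (DiD)** at the county level, where treated
  counties (those of the policy state) are compared with control-state
  counties before and after the policy.

## Synthetic control

### Nested optimization

For treated unit *1* with donors *j = 1…J*, predictors enter a k-vector
`X1` and a k×J matrix `X0`. Each predictor row is z-scored across
{treated ∪ donors} so the predictor weights `V` are comparable across
predictors of different scales; zero-variance rows are dropped. For fixed
`V` the donor weights solve

    W*(V) = argmin_{W ≥ 0, ΣW = 1} (X1 − X0 W)ᵀ diag(V) (X1 − X0 W)

and `V` itself is chosen on the k-simplex to minimize the mean squared
*prepolicy outcome* discrepancy `pre-MSPE(V) = ‖Z1 − Z0·W*(V)‖²/T0`, where
`Z1`/`Z0` are the prepolicy outcome paths. The per-year gap is
`Y1(t) − Σ_j W_j Y0_j(t)` and the effect size is

    Δ = mean(postpolicy gaps) − mean(prepolicy gaps),

i.e. the pre-to-post change of the treated unit minus that of its synthetic
control. Means are taken over all available pre and post years — the minimal
reading of a "pre- to postpolicy change" with two postpolicy years.

**Inner solver.** The donor-weight problem is a small convex QP over the
probability simplex. It is solved exactly by an active-set method in Gram
form (`G = X0ᵀ diag(V) X0`): start at the best single-donor vertex,
alternately solve the equality-constrained KKT system on the current support
and exchange support members by the sign of the reduced gradient. The method
is deterministic, handles corner solutions exactly, and is validated against
exhaustive grid search (step 1e-3, objective agreement within 1e-4) on random
instances. Singular KKT systems (collinear donors) fall back to a
pseudo-inverse, keeping the solution deterministic. Solver tolerance is 1e-8
on the simplex constraint; support-exchange tolerance 1e-9 relative.

**Outer search.** `pre-MSPE(V)` is piecewise-smooth but not convex, so `V`
is optimized by derivative-free multi-start: Nelder–Mead (relative tolerance
1e-9, ≤300 iterations; golden-section for k = 2) on the
softmax-parameterized simplex, started from the uniform vector, every
simplex vertex, and `n_random_starts` (default 5) Gaussian draws made under
a fixed private seed (20160701), so repeated calls are bit-identical and the
caller's RNG stream is untouched. The uniform vector and all vertices are
also evaluated directly, so the returned `V` is never worse than uniform
weighting. With k = 1 the outer problem is trivial (`V = 1`).

**Predictor block.** By default the outcome enters as its prepolicy mean
(matching on average prepolicy outcomes), plus each requested covariate
averaged over the prepolicy window. With one predictor the inner problem is
heavily degenerate — any weight mix matching the prepolicy mean is optimal —
so the package also offers `outcome_lags = TRUE`, entering the outcome year
by year; this pins the weights down from the whole prepolicy path and is
what the recovery tests use. Donors missing any predictor or any year of the
outcome are excluded and logged, as are all treated-side data requirements.

**Stepwise covariate selection.** Candidate covariates are added greedily,
scored by a validation MSPE: the fit is recalibrated on the prepolicy years
excluding the last `holdout_years` (default 1) and evaluated on those
held-out years. Selection stops when no candidate improves the validation
MSPE by more than 1e-6; ties break toward the earlier candidate in the list.
The exact cross-validation split used in the original analyses is not
public, so this holdout scheme is the package's own documented stand-in.

### Placebo inference

Treatment is reassigned to each control state in turn; the full procedure
(same predictor set) is refit with the remaining controls as donors. The
true treated state is excluded from every placebo's donor pool because it is
exposed post-policy and would contaminate the counterfactual. Effects are
oriented by the prespecified direction of the hypothesis (coverage up, NME
down, ME up); the treated rank is `1 + #{placebos ≥ treated}` — ties count
against the treated unit, the conservative choice — and the result is
*meaningful* when `100·rank/n ≤ 5`. No prepolicy-fit (MSPE-ratio) filtering
of placebos is applied by default, matching the practice of reporting raw
counts of evaluated states; an optional cutoff flag exists. Whether signed
or absolute effects should be ranked is not settled; signed ranking in the
prespecified direction is used, per the wording of the decision rule.

## County difference-in-differences

The design is the 2×2 specification: intercept, treated (counties of the
policy state), post (year ≥ policy year), treated×post (the policy effect
β₃), plus covariates in their natural units (a year-fixed-effects variant
sits behind `year_fixed_effects = TRUE`). OLS is solved by QR; rank
deficiency raises an error naming the collinear columns. The covariance is
the CR1 clustered sandwich

    V = c · (XᵀX)⁻¹ [ Σ_g Xgᵀ e_g e_gᵀ Xg ] (XᵀX)⁻¹,
    c = G/(G−1) · (n−1)/(n−p)

clustered by county; with singleton clusters it reduces exactly to HC1. CIs
and p-values use t with `G − 1` degrees of freedom, the standard
conservative convention for clustered inference (the original report does
not state its choice). CR1 rather than CR2/CR3 because it is the common
default in applied work; the brute-force sandwich identity is enforced in
tests to 1e-10, and `sandwich::vcovCL` serves as an independent
cross-check. The parallel-trends diagnostic tabulates group means by year
and reports the difference of OLS slopes on prepolicy group means.

### Cleaning rules

* counties with population below 65,000 are excluded (covariate
  availability rationale), using the most recent non-missing population;
* a county that never reports overall coverage but reports MMR has overall
  coverage set to MMR for all its years — a per-unit decision, logged per
  year so `overall_only_subanalysis()` can drop all counties of proxied
  states;
* for a given outcome, units whose missing fraction exceeds
  `max_missing_fraction` (default 0.2) are excluded; remaining gaps are
  filled by within-unit linear interpolation over year with nearest-value
  extension at the edges. The original impute-or-exclude appendix does not
  name its method or threshold; linear interpolation was chosen because it
  is deterministic, order-preserving and leaks nothing across units, and
  the threshold is configurable. Both operations are idempotent, never
  alter an observed cell, and log every repair in a `cleaning_report`.

## The synthetic data generator

Outcomes follow an interactive factor model per unit *i* and year *t*:

    Y_it = μ + α_i + δ_t + λ_iᵀ f_t + τ·1{treated, t ≥ policy} + ε_it,

with unit effects α (between-unit sd per outcome), a common linear trend
plus year shocks δ, `n_factors` latent factors (loadings scaled to the
between-unit sd; the factor term is what makes a *synthetic control* rather
than a two-way model the right estimator, and setting `treated_in_hull =
TRUE` places the treated unit's α and λ in the convex hull of three donors
so the identifying assumption holds exactly), AR(1) noise ε (innovation sd
`noise_sd`, per outcome if named), and clamping to [0, 100] — the one
nonlinearity. County panels nest counties in states with a state random
effect calibrated so the within-state intraclass correlation of outcomes
equals `county_icc`; county populations are log-normal (median ≈ 60,000) so
the 65,000 filter binds; and with `effect_heterogeneity > 0` the injected
county effect scales with the unit's room to move (lower prepolicy coverage
→ larger gain; higher prepolicy exemptions → larger decline), emulating the
observed hot-spot pattern. Covariates are drawn correlated with the coverage
unit effects so predictor selection has signal. Defaults quote the printed
2015 state baselines (coverage 94.2 ± 2.5, NME 2.2 ± 1.3, ME 0.3 ± 0.2 pp)
and the headline county effects (+4.3 / −3.9 / +2.4 pp) as injected truths.

**What the generator does not emulate:** reporting-rule changes and
measurement-protocol differences across states and years, serially
correlated policy spillovers, interference between states, and the actual
covariate joint distribution. Passing recovery tests therefore shows the
estimators are correct under their own assumptions, not that those
assumptions hold in any particular real panel.

**Bounded outcomes and recovery conditions.** The printed baselines sit so
close to the bounds that the default injected effects are partially
truncated (94.2 + 4.3 pp crosses 100; 2.2 − 3.9 pp crosses 0). That is
faithful to real coverage data — post-policy NMEs really do pile up near
zero — but it means recovery of the *injected* τ is attenuated under the
printed baselines. The parameter-recovery tests therefore run at baselines
with headroom (coverage 85 ± 3, NME 6 ± 2 pp), chosen once so that what is
being tested is the estimator, not the truncation. Likewise the DiD
coverage/size properties run with `n_factors = 0`, `county_icc = 0` and
`effect_heterogeneity = 0`: panel-wide factors and a shared treated-state
shock violate the independence-across-clusters assumption of
county-clustered errors and would test the data-generating process rather
than the estimator.

## Problem sizes and runtime choices

The test suite exercises: 50 random QP instances against exhaustive grid
search; exact recovery on a 15-state noiseless hull panel; 200 noisy
replicates (σ = 0.5) for mean recovery of a 3 pp effect within 0.15 pp; 200
null panels of 20 states for placebo calibration against the exact binomial
band of the top-5% rule; 200 replicates of a 57-treated/≈250-control county
panel for 95% CI coverage of a 4.3 pp effect; 500 null replicates on a
balanced design (60 treated of ≈170 clusters) for test size; and constructed
fixtures for every cleaning rule. These sizes keep the full suite within a
few minutes on one CPU while leaving Monte-Carlo error well inside the
asserted bands.

## Known limitations

* With few treated clusters (a single treated state's counties among many
  control states), CR1 + t(G−1) inference over-rejects — the familiar
  few-treated-clusters problem; a wild cluster bootstrap is out of scope.
  The size property is therefore evaluated on a balanced design.
* Predictor z-scoring is computed across the current unit pool, so
  leave-one-out refits change the standardization slightly; a zero-weight
  donor is exactly inert only in the exact-recovery regime.
* With the default mean-only outcome predictor the donor weights are not
  unique; the active-set solver resolves the tie deterministically, and
  `outcome_lags = TRUE` removes the degeneracy.
* The outer V-search is a heuristic over a non-convex landscape; it is
  guaranteed no worse than uniform weights and is validated against simplex
  grids at small k, but global optimality at large k is not certified.
* No augmented/penalized synthetic-control variants, no conformal or
  asymptotic SC inference, no event-study dynamics, no enrollment weights.
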