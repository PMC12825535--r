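---
title: "Methods: pre-diagnostic proteome analysis with prediagprot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre-diagnostic proteome analysis with prediagprot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

prediagprot analyses baseline-only plasma proteomics (Olink-style NPX
values, approximately standard normal per protein) against a rare
incident-cancer outcome observed over long follow-up. This vignette is
the package's account of the models it fits, the defaults it chooses and
why, what the synthetic generator does and does not emulate, and the
known limitations.

## The data model

Two tables drive everything. The *cohort table* has one row per
participant: the nine baseline covariates (age, sex, ethnicity,
deprivation index, smoking, alcohol, BMI, hypertension, diabetes,
optionally serum creatinine), a positive follow-up time in years, an
event flag, and — for cases — the lead time, i.e. years from blood draw
to diagnosis (equal to follow-up time at diagnosis). The *protein
matrix* is participants × proteins with missing cells allowed before
imputation. Preprocessing applies an ordered exclusion cascade (prior
cancer first, then any missing covariate — a row failing both is counted
once, at the first step), drops proteins missing in strictly more than
20% of rows, imputes the rest by protein-axis k-nearest-neighbour
averaging (k = 10), and splits the cohort 80/20 into derivation and
replication sets by simple seeded randomisation with floor rounding and
no stratification — the derivation/replication case counts are then left
to chance, which matches how such splits are typically drawn.

The kNN rule: a missing cell (i, p) is filled with the mean over the k
proteins nearest to p of their observed values in row i. Proximity is
Euclidean distance over rows where both proteins are observed, divided
by the number of such rows, so pairs with different overlap are
comparable; a protein with no complete peer falls back to its mean with
a warning. The test suite checks this cell-for-cell against an
exhaustive brute-force oracle on randomized matrices up to 10 × 10.

## Proteome-wide Cox scan

Each protein is standardized to SD 1 *within the analysis set* and
enters a Cox model alone with the covariates (Efron tie handling).
Reporting per-SD hazard ratios makes planted-effect recovery
well-defined; note that absolute HR magnitudes depend on this scaling
choice, so they are comparable within a run but not to results computed
on another scale. Multiplicity is controlled two ways over the same
family: Bonferroni at α/M (M defaults to the number of proteins actually
tested and can be overridden to reproduce a declared family such as
0.05/2911 = 1.7 × 10⁻⁵) and Benjamini–Hochberg q-values. Proportional
hazards is checked per protein with the Schoenfeld-residual test,
flagged at p < 0.01. Two sensitivity variants re-run the scan: dropping
cases diagnosed within 2 years of baseline entirely (reverse causation),
keeping the declared M; and augmenting the covariate set (e.g.
creatinine). Failed or degenerate fits (constant protein,
non-convergence) are reported with NA statistics rather than silently
dropped, and never shrink the declared family.

## Lead-time trajectories

Only baseline measurements exist, so the lead time of each case is used
as a progression surrogate: a protein's "trajectory" is the cross-
sectional regression of case z-scores on lead time. Steps and defaults:

* **Matching** — 10 event-free controls per case, exact on sex, nearest
  on baseline age (absolute difference, no caliper), without replacement
  across cases; cases are processed in seeded random order and ties are
  broken by the same stream, so the assignment is deterministic given
  the seed. An exhausted pool yields fewer controls and a warning.
* **Residualization** — per protein, ordinary least squares of NPX on
  the covariates, fitted on controls only and applied to everyone.
  Fitting in controls keeps case-specific signal out of the adjustment;
  a planted case-only shift survives it (tested).
* **z-scores** — per case against its own matched controls, SD with the
  n − 1 denominator. Invariant to any affine transform applied uniformly
  to a case and its controls.
* **LOESS** — local linear regression (degree 1, tricube weights, span
  0.75) on a 15 → 0 year grid in 0.25-year steps, truncated to the
  observed lead-time range with no extrapolation. Degree 1 is the
  default because edge lead times are case-sparse and local quadratics
  oscillate there; degree 2 is exposed for parity with other
  implementations. Degree-1 LOESS is exact on linear and constant data,
  which the tests exploit as an oracle.
* **Abnormality** — the 0.45 z-unit threshold is applied to the LOESS
  predictions (not the raw per-case z-scores, which would be dominated
  by noise). All exceedance runs are recorded; the *sustained onset* is
  defined as the earliest lead time of the final run provided that run
  persists to the end of the observed grid, making verbal statements
  like "became abnormal but reverted before diagnosis" computable.
* **Clustering** — pairwise Chebyshev (maximum) distance between curves,
  complete linkage, tree cut at k = 4; k-means on the raw prediction
  vectors (25 seeded starts) as a stability check. Identical curves tie
  at distance zero and resolve by input order.

## Four-way mediation decomposition

For exposure A (continuous exposures standardized to mean 0, SD 1;
binary ones coded 0/1 — an exposure already 0/1-valued is left on its
natural scale so both paths agree), mediator M and covariates C, the
package fits

* mediator model: `M = β₀ + β₁A + β₂ᵀC + ε`, `ε ~ N(0, σ²)` (OLS, σ²
  the residual variance), and
* outcome model: Cox log-hazard `θ₁A + θ₂M + θ₃AM + θ₄ᵀC`,

and treats the hazard ratio as a relative risk (rare outcome; a warning
fires above a 5% event fraction). With
`g(a,m) = exp(θ₁a + θ₂m + θ₃am)`,
`μ(a′) = β₀ + β₁a′ + β₂ᵀc` and the normal moment-generating function,

`Q(a,a′) = E[g(a, M_{a′})] = exp(θ₁a)·exp((θ₂+θ₃a)μ(a′) + ½(θ₂+θ₃a)²σ²)`,

the excess-relative-risk components relative to `D = Q(a*,a*)` are

```
te      = [Q(a,a)  − Q(a*,a*)] / D
cde     = [g(a,m*) − g(a*,m*)] / D
int_ref = [Q(a,a*) − Q(a*,a*) − g(a,m*) + g(a*,m*)] / D
int_med = [Q(a,a)  − Q(a*,a)  − Q(a,a*) + Q(a*,a*)] / D
pie     = [Q(a*,a) − Q(a*,a*)] / D
```

These sum to the total effect algebraically, and the tests hold the sum
to 1e-10 and hold Q against independent Gauss–Hermite quadrature to
relative error 1e-8. Reference levels default to a = 1, a* = 0, m* = the
marginal sample mean of the mediator, and covariates at their sample
means (modal category for factors); all are configurable. The mediation
proportion is PIE/TE (with (PIE+INTmed)/TE also reported), and it is
invariant to affine rescaling of the mediator.

One property worth stating precisely, because intuition from the
difference scale misleads: setting θ₃ = 0 does **not** zero the two
interaction components on this scale. A model multiplicative in A and M
without a product term still has additive-scale interaction, so INTref
and INTmed are genuinely nonzero there (they match the model-free
quadrature integrals, and vanish only to first order in small effects —
both tested). By contrast β₁ = 0 does zero PIE and INTmed exactly.

Uncertainty is a seeded nonparametric bootstrap (default B = 500,
percentile intervals, both models refitted per resample with the
reference levels held at their point-estimate values); p-values use the
normal approximation with the bootstrap SE. The delta method was not
implemented: the bootstrap needs no hand-derived gradients and its
coverage is itself verified by simulation (≥ 90% at n = 20,000,
B = 200). Mediation is "significant" when both TE and PIE have p < 0.05.

Mediator screening takes proteins significant on both legs (exposure →
protein OLS and protein → outcome Cox, α = 0.05 each). For aggregation,
mediators with opposing PIE and CDE signs are excluded, the rest are
standardized and decomposed by PCA; components with correlation-scale
eigenvalue > 1 are retained (Kaiser; if none, the first component with a
warning), and each standardized score is run back through the
decomposition. With several retained components the combined proportion
is reported as the sum of per-component proportions and flagged
approximate — the scores are orthogonal but the decomposition is
nonlinear; with a single component it is exact. Components are entered
one at a time (not jointly); an optional filter on INTmed significance
is available for analyses that exclude interaction-driven mediators, but
it is off by default.

## Risk models

The clinical model is bidirectional stepwise-AIC Cox from the full
candidate set (deterministic given data). The protein model takes the
FDR-significant scan hits, fits LASSO-Cox with the penalty chosen by
10-fold cross-validated partial-likelihood deviance at its minimum, and
refits the surviving proteins unpenalized — selection-then-use, which is
what a discrete reported protein panel implies. The combined model is
stepwise-AIC over the union of the two feature sets. Evaluation is
strictly frozen-model: `evaluate_risk_model()` only computes linear
predictors on the evaluation split, never refits.

Metrics: Harrell's C (via `survival::concordance`) with a normal CI;
IPCW cumulative-cases/dynamic-controls AUC at integer horizons 2–10
years, with case weights 1/Ĝ(Tᵢ⁻) and control weights 1/Ĝ(τ) from the
censoring Kaplan–Meier (undefined groups give NA, never 0 or 1); IDI at
the 10-year horizon as the difference in IPCW discrimination slopes of
predicted 10-year risks (Breslow baseline from the training fit) — zero
by construction against itself and antisymmetric; a paired-bootstrap
(B = 500, seeded) two-sided p for the C-index difference versus a
reference model; and a Youden-optimal cutoff at 10 years, computed on
the derivation split and applied unchanged to replication for the
Kaplan–Meier/log-rank split. A single-marker path wraps a univariate Cox
fit in the same evaluation, which is how a lone early-rise biomarker
shows its characteristic near-diagnosis AUC gain (2-year AUC above
10-year AUC).

## The synthetic generator

`simulate_cohort()` draws covariates from simple documented marginals
(age ~ U(40, 70), 47% male, 94% white, BMI ~ N(27, 4.5²), 45% ever
smokers, deprivation ~ N(0, 3²), comorbidity Bernoullis), an iid
standard-normal NPX matrix, and event times from an exponential
proportional-hazards model whose linear predictor contains the declared
signal proteins, the exposure and any mediator proteins (mediator =
β₁·A + N(0, 1)). The baseline hazard is calibrated by root-finding so
the expected cumulative incidence under the realized linear predictors
and censoring times matches the configured rate (default 0.34%);
administrative censoring is drawn uniformly over ±1.26 years around the
configured 11.76-year median, reproducing a biobank-like follow-up
spread. Case proteins assigned a trajectory archetype have the archetype
shape at the case's lead time added to their NPX, controls carry shape
zero, and an MCAR mask is applied last.

The four archetype shapes are qualitative stand-ins chosen so the 0.45
threshold separates regimes: (1) 3·exp(−bt) with z(15) = 1 (early
abnormal, rising to 3 at diagnosis); (2) constant 0.8; (3) logistic step
centred 3 years pre-diagnosis rising 0 → 0.9 (scale 0.75 y); (4)
Gaussian bump centred at 15 years, height 0.9, SD 4 years. No published
quantitative curve parameters exist for such clusters, so recovery tests
assert cluster separation and threshold behaviour, not exact curves.

What the generator does *not* emulate — and hence what passing tests do
not establish about real cohorts: covariate–covariate and
protein–protein correlation structure, confounding of the
exposure–mediator–outcome pathway, informative censoring, competing
risks, non-MCAR missingness, batch or panel effects, and subtype
heterogeneity. Recovery results here certify the estimators against
their own assumptions, not robustness to their violation.

## Numerical choices and problem sizes

Ties in event times use Efron's approximation throughout. LOESS uses
direct (non-interpolated) surface evaluation so linear inputs are
reproduced to machine precision. Chebyshev distance ties are broken by
input order; k-means uses 25 seeded restarts. Stage seeds in the
pipeline are derived deterministically from one global seed, so enabling
or re-parameterising one stage never perturbs another stage's stream.
The statistical test suite and the acceptance script run their
calibration studies at deliberately chosen sizes — e.g. 200 null scans
of 200 proteins at n = 1,000 for family-wise error, 50 replicates of
n = 20,000 with B = 200 for bootstrap coverage, 40 replicates for
planted-HR recovery, 24 noisy curves for clustering recovery — sizes at
which the binomial noise of the pass criteria is small relative to the
margins being asserted.

## Pipeline

`run_pipeline()` executes simulate → preprocess → scan → trajectories →
mediate → riskmodel from a single validated YAML/list config, writing
only delimited text and JSON (diff-able, no binary intermediates), with
a manifest of per-stage seeds and output digests; a failing stage halts
the run with its name and keeps earlier outputs. `render_report()`
assembles whatever stage outputs exist into one markdown document and
notes stages that did not run. The functions are the interface; a thin
`inst/scripts/prediagprot` wrapper exposes `run` and `report` verbs for
shell use.

## Limitations

The mediation decomposition inherits the rare-outcome RR≈HR
approximation and a correctly specified normal mediator model; the
trajectory axis is a cross-sectional surrogate (each case contributes
one point at one lead time), so curves describe population-level
composition, not within-person change; LASSO selection is not
inferentially corrected (refit p-values are post-selection); and IDI is
horizon- and scale-dependent, so only within-run comparisons are
meaningful.
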