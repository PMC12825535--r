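# prediagprot

Analysis toolkit for **pre-diagnostic plasma proteomics** in prospective
cohorts with a rare time-to-event outcome — the setting where thousands of
Olink-style NPX protein measurements are taken once at baseline and
participants are followed for a decade for an incident cancer diagnosis.
It is aimed at biostatisticians and molecular epidemiologists who want the
full analysis chain as tested, reusable functions rather than one-off
scripts.

The package implements five connected pieces of methodology:

1. **Proteome-wide Cox scan.** One proportional-hazards model per protein
   (per-SD NPX, Efron ties), adjusted for the nine baseline covariates
   (age, sex, ethnicity, deprivation index, smoking, alcohol, BMI,
   hypertension, diabetes), with Bonferroni control at `α / M`,
   Benjamini–Hochberg q-values, Schoenfeld-residual diagnostics
   (violation at p < 0.01), a reverse-causation sensitivity scan dropping
   cases diagnosed within 2 years, and an extra-covariate (e.g. serum
   creatinine) sensitivity variant.
2. **Lead-time trajectories.** With baseline-only measurements, the time
   from blood draw to diagnosis is used as the progression axis: cases
   are matched to 10 event-free controls by sex and nearest age, NPX is
   residualized on covariates fitted in controls, case z-scores are taken
   against each matched-control set, LOESS (degree 1, span 0.75) is fit
   over a 15 → 0 year lead-time grid, abnormality (z > 0.45) crossings
   and sustained onsets are called, and curves are clustered by
   Chebyshev-distance complete-linkage hierarchical clustering into four
   trajectory families (k-means as a sensitivity route).
3. **Four-way causal mediation.** For an exposure A (standardized BMI, or
   ever-smoking 0/1), a protein mediator M with a linear mediator model
   `M = β₀ + β₁A + β₂ᵀC + ε, ε ~ N(0, σ²)`, and a Cox outcome model
   `log h = θ₁A + θ₂M + θ₃AM + θ₄ᵀC`, the total effect on the excess
   relative risk scale is decomposed exactly as

   `TE = CDE + INTref + INTmed + PIE`

   using the closed-form normal-mediator expectation
   `Q(a,a′) = exp(θ₁a)·exp((θ₂+θ₃a)μ(a′) + ½(θ₂+θ₃a)²σ²)`.
   Uncertainty comes from a seeded nonparametric bootstrap refitting both
   models; mediation is called significant when both TE and PIE have
   p < 0.05. Multiple mediators are aggregated by PCA (Kaiser criterion,
   opposing-sign PIE/CDE exclusion) and the component scores fed back
   through the same decomposition.
4. **Risk models.** Clinical (stepwise-AIC Cox), protein
   (FDR hits → cross-validated LASSO-Cox → unpenalised refit), and
   combined (stepwise over the union) models, evaluated frozen on a held
   out split with Harrell's C, IPCW time-dependent AUC over 2–10 year
   horizons, IDI at 10 years, a paired-bootstrap C-index comparison,
   and a Youden-cutoff Kaplan–Meier split; plus a single-marker path.
5. **Synthetic cohort generator.** A seeded generator emulating the
   assumed data structure — ~0.3% cumulative incidence over ~11.8 years
   median follow-up, standard-normal NPX with MCAR gaps, four planted
   lead-time trajectory archetypes, proportional-hazards signal proteins,
   and an exposure → mediator → hazard pathway — with a ground-truth
   record so every stage has recovery and calibration tests.

## Worked example

```r
library(prediagprot)

cfg <- sim_config(
  n_participants = 5000, n_proteins = 50, event_rate = 0.02,
  signal_log_hr = c(PROT0001 = log(3)),
  archetype_assignments = c(PROT0001 = 1L),
  seed = 42)
sim <- simulate_cohort(cfg)

scan <- pwas_scan(sim$cohort, sim$proteins)
head(scan[order(scan$p), c("protein", "hr", "ci_low", "ci_high", "p")], 3)
#>     protein        hr    ci_low    ci_high             p
#> 1  PROT0001 9.9388014 8.1036571 12.1895301 9.693657e-108
#> 2  PROT0002 1.2463607 1.0277502  1.5114714  2.521171e-02
#> 35 PROT0035 0.8075279 0.6645638  0.9812471  3.152436e-02
```

The planted protein is recovered with a p-value far beyond the
Bonferroni threshold while the remaining proteins are null; its fitted
per-SD hazard ratio (9.94) exceeds the planted baseline HR of 3 because
the early-rise trajectory shift adds further case/control separation.
Its trajectory:

```r
matched <- match_controls(sim$cohort, ratio = 10, seed = 1)
adj <- residualize(sim$proteins, sim$cohort)
z <- zscore_cases(adj[, "PROT0001", drop = FALSE], matched)
lead <- sim$cohort$lead_time[match(rownames(z), sim$cohort$participant_id)]
traj <- fit_trajectories(z, lead)
traj$onset
#> PROT0001
#>    12.25
```

The early-rise archetype is called abnormal (z > 0.45) across the whole
observed window, with sustained onset at the earliest observed lead time
(12.25 years here — the longest follow-up in this simulated cohort; the
curve is never extrapolated beyond the data). The same
objects drive clustering, mediation and risk modelling; or run everything
from one config:

```r
run_pipeline("run.yaml")   # simulate -> preprocess -> scan -> ... -> report
render_report("out/")
```

A thin shell wrapper for the pipeline lives at
`inst/scripts/prediagprot` (`prediagprot run --config run.yaml`).

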