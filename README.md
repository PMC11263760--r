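# akitrace

Temporal detection of drug-induced acute kidney injury (AKI) in multicenter
electronic health records.

`akitrace` is an end-to-end R pipeline for pharmacovigilance of
drug-induced nephrotoxicity in observational EHR data organised as an
OMOP-CDM-style table subset (person, measurement, drug_exposure,
condition_occurrence, procedure_occurrence). It is aimed at clinical
epidemiologists and ML practitioners who want a tested, reproducible
implementation of the full chain from cohort phenotyping to interpretable
sequence modelling — runnable entirely on synthetic data, since hospital
EHRs cannot be shared.

## What it implements

1. **Cohort phenotyping.** For each of five target drugs (acetaminophen,
   vancomycin, naproxen, celecoxib, acyclovir), the index date is the first
   exposure. AKI is a serum-creatinine (SCr) rise to 2× baseline within 60
   days of index; the upper limit of normal (ULN = 1.2 mg/dL) substitutes
   for the baseline, giving a fixed event threshold of 2.4 mg/dL. Inclusion
   requires a visit record ≥ 30 days before index and ≥ 2 SCr tests in the
   60-day pre-observation window; any pre-observation SCr above the ULN
   excludes the patient.
2. **Propensity matching.** Logistic-regression propensity scores on
   standardized age, sex and baseline SCr; greedy 1:3 nearest-neighbour
   matching without replacement; standardized-mean-difference balance
   reports.
3. **Featurization.** Candidate predictors chosen by paired index-vs-onset
   tests (paired *t* for labs, McNemar for binary variables); events pivoted
   to fill-imputed daily grids (forward fill for labs/diagnoses, zero fill
   for drugs/procedures); 28-day windows at 14-day stride, labelled by
   whether AKI onset falls in the 14 days after the window; person-level
   stratified 6:2:2 train/validation/test splits.
4. **Interpretable multivariable LSTM.** Each variable keeps its own
   hidden-state block (variable-wise gates), with temporal attention
   α\[v,t\] over time steps within each variable and variable attention
   β\[v\] over variables, mixed into the prediction:

       j_t[v] = tanh(W_v h_{t-1}[v] + U_v x_t[v] + b_v)
       i,f,o  = σ(gates over [h_{t-1}[v]; x_t[v]])        (per variable)
       α[v,t] ∝ exp(score_v(h_t[v]))                      (sums to 1 over t)
       β[v]   ∝ exp(score([g_v; h_T[v]]))                 (sums to 1 over v)
       p      = σ(Σ_v β[v] · head_v([g_v; h_T[v]]))

   Training: Adam, lr 1e-3, batch 64, ≤ 200 epochs, early stopping after 20
   epochs without validation-loss improvement. Forward pass, analytic
   backpropagation and the optimiser are implemented in vectorized base R
   and verified against a hand-unrolled oracle and finite differences.
5. **Evaluation & interpretation.** AUROC (Mann–Whitney and trapezoid),
   AUPRC, accuracy/precision/F1, stratified bootstrap CIs; β-weighted
   aggregation of attention into a variable × week importance surface with
   heat-map export; onset-day medians/IQRs with pairwise tests; χ²/Welch
   group comparisons and repeated-measures ANOVA.
6. **Synthetic multi-site generator.** Seeded OMOP-style bundles with
   planted case/control structure: confounded case assignment (age, sex,
   baseline SCr), drug-specific lognormal onset-day distributions
   calibrated to their 60-day-truncated medians, prodromal laboratory drift
   before onset (lymphocytes/albumin/hemoglobin fall; urine pH and
   prothrombin time rise), irregular lab sampling, and optional "spoiler"
   patients that exercise every exclusion rule.

## Worked example

```r
library(akitrace)

cfg <- run_config(
  sites  = list(site_sim_config("SH", 800, drug_mix = c(acyclovir = 1), seed = 21)),
  drugs  = "acyclovir",
  hyper  = imv_hyperparams(epochs = 40, patience = 10, seed = 9),
  min_cases = 20, seed = 33)
res <- run_pipeline(cfg)
res
#> <pipeline_result> 1 completed cells
#>   SH:acyclovir                 cases    44  AUROC(test) 0.902
res$onset$by_drug
#>        drug  n  q1 median    q3
#> 1 acyclovir 44 9.5     22 37.25
head(res$pooled_attention$weekly, 3)
#>                week_-4    week_-3    week_-2    week_-1
#> urine_ph    0.03109953 0.03430600 0.03773852 0.03971311
#> lymphocytes 0.03299324 0.03530009 0.03675889 0.03780492
#> ...
```

The cohort of 800 exposed patients yields 44 AKI cases; after 1:3 matching
and featurization the model reaches a held-out AUROC of 0.90, the acyclovir
onset-day median lands near its configured 23 days, and the aggregated
attention surface rises toward the final pre-onset weeks for the
prodromally drifting labs — the qualitative signature the pipeline is
designed to surface. Exact numbers vary with the seeds shown.

Each stage is also callable on its own (`generate_site()`,
`apply_eligibility()`, `match_cohort()`, `build_grid()`, `make_windows()`,
`imv_train()`, `metrics_report()`, `aggregate_attention()`, ...), and
`inst/scripts/run_pipeline.R` wraps `parse_config()`/`run_pipeline()` for
shell use with a YAML config.

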