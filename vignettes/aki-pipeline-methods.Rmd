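---
title: "Methods: phenotyping, matching and interpretable sequence modelling of drug-induced AKI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotyping, matching and interpretable sequence modelling of drug-induced AKI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(akitrace)
```

This vignette is the package's account of its science: the models and
rules it implements, the tunable parameters and their defaults, what the
synthetic generator does and does not emulate, and the design choices made
where the design was genuinely open.

## 1. The AKI phenotype

The outcome is drug-induced acute kidney injury operationalised on serum
creatinine (SCr): an event is the first SCr at or above `ratio` × baseline
in the half-open follow-up interval `(index, index + 60 d]`, where the
index date is the patient's first exposure to the target drug. Following
KDIGO-style practice when a true baseline is unreliable, the default
`baseline_policy = "uln_fixed"` substitutes the upper limit of normal
(ULN, 1.2 mg/dL) for the baseline, so the event threshold is a fixed
`2 × 1.2 = 2.4` mg/dL. This is internally consistent because eligibility
already excludes anyone whose pre-index SCr ever exceeds the ULN: every
retained patient's unobserved true baseline is at most the ULN, so the
fixed threshold is conservative. The observed-mean variant
(`"observed_mean_capped"`, baseline = `min(mean(pre-obs SCr), ULN)`) is
kept configurable for sensitivity analyses.

Eligibility is checked in a fixed order, and each excluded patient carries
exactly one reason: `no_prior_visit` (no recorded event ≥ 30 days before
index), then `insufficient_preobs_scr` (fewer than 2 SCr tests in
`[index − 60 d, index)`), then `preobs_scr_above_uln`. The pre-observation
window excludes the index day itself, and an SCr spike on the index day is
not attributed to the drug — both half-open-interval readings of rules
that leave endpoint handling open.

A person exposed to two target drugs appears independently in both drug
cohorts; all models are per-(site, drug).

## 2. Propensity matching

Cases and controls are matched 1:3 on age, sex (0/1-encoded) and baseline
SCr (mean of pre-index values). Covariates are jointly standardized
(population SD); the propensity model is a logistic regression fitted by
damped Newton–Raphson to gradient norm < 1e-8, with an L2 penalty of 1e-6
that leaves well-posed problems numerically unchanged but bounds the
solution (with a warning) under perfect separation. Matching is greedy
nearest-neighbour on the propensity score, **without replacement**, cases
processed in descending score order, distance ties broken toward the
smaller person id — including ties hidden inside runs of equal scores on
either side of the case. No caliper is applied by default. Matching runs
within site and results are pooled, mirroring per-site reporting of
matched groups. Balance is summarised by the absolute standardized mean
difference `|m₁ − m₀| / √((s₁² + s₀²)/2)` before and after matching.

Open points resolved here: whether the source analysis matched with or
without replacement is unstated — without replacement is the conservative
choice and makes the achieved ratio a diagnostic (reported, not forced to
exactly 3.0, since a shallow control pool can leave late cases short).

## 3. Featurization

Candidate predictors are screened on cases only, pairing each variable's
value at the index date with its value at the AKI onset date: paired
two-tailed *t* test for continuous labs, McNemar's `(b−c)²/(b+c)` for
binary variables, selection at α = 0.05 without multiplicity correction
(BH-FDR available by flag). Variables with fewer than 10 complete pairs
are skipped. SCr itself is excluded from model inputs because the label is
derived from it.

Events are pivoted to per-person daily grids (day 0 = index): same-day
duplicate labs are averaged (a declared choice; last-taken is equally
defensible), labs and diagnoses are carried forward from the last
observation, days before the first observation take the last pre-index
value or, failing that, the cohort median (flagged); drugs and procedures
are zero-filled binary indicators. Windows are 28 days long with 14-day
stride, starting at day 0. A window is emitted only if it fits before the
case's onset (or the control's follow-up end) — no window ever contains a
post-onset day — and is labelled positive iff onset falls in
`(window_end, window_end + 14 d]`. The 14-day horizon is the most literal
reading of "predicting one cycle ahead" given the 2-week stride; it is a
parameter, not a fact about the data. Splits are 6:2:2 **by person**
(stratified by case status, seeded), so no patient contributes windows to
two splits; continuous inputs are standardized with the training split's
scaler.

## 4. The interpretable multivariable LSTM

Each of the V input variables keeps its own d-dimensional hidden block
(default d = 4; the hidden size of the original study is unstated, and at
desk scale larger blocks only slow training). The candidate update for
block v sees only variable v's input and previous block. The
input/forget/output gates are **variable-wise** as well, affine in
`[h_{t−1}[v]; x_t[v]]`. The design was genuinely open between shared gates
over the flattened state and fully variable-wise gating; we began with
shared gates and found they defeat attribution: the model separates
planted signal perfectly (validation AUROC ≥ 0.95 in 10/10 runs) while
the variable attention ranks the signal variable first in only 4/10,
because shared gates let every block encode every variable. With
variable-wise gates a block can only ever carry its own variable's
history, and the rank-first rate rises to 9/10 with unchanged
discrimination — so variable-wise gating is the package's choice.

Attention: a per-variable temporal scorer (tanh layer, d → 1) gives
α[v,·] by softmax over time; the context `g_v = Σ_t α[v,t] h_t[v]` and
final block `h_T[v]` feed a shared variable scorer for β (softmax over
variables) and per-variable linear heads, mixed as
`p = σ(Σ_v β[v]·head_v([g_v; h_T[v]]))`.

Training minimises binary cross-entropy with Adam (lr 1e-3, batch 64,
≤ 200 epochs), early-stopping on validation loss with patience 20 and
returning the best-validation-epoch parameters. Because positive windows
are rare (one per case at most, against several control windows), the
loss weights positives by `n_neg/n_pos` by default; a flag disables this
for a literal unweighted reading. Mini-batch order is seeded;
single-threaded runs are bit-reproducible. Gradients are analytic
(reverse-mode, derived by hand) and are tested against central finite
differences; the forward pass is tested against an independent scalar
unrolled oracle at 1e-8.

## 5. Evaluation and attention aggregation

AUROC uses the midrank Mann–Whitney form (ties ½), with a trapezoid
integration kept as a second route — the two must agree to 1e-12. AUPRC
uses the step rule (average precision with tied scores grouped).
Accuracy/precision/F1 are computed at threshold 0.5 by default (the
source threshold is unstated). The AUROC CI is a stratified percentile
bootstrap (seeded, 1000 resamples) rather than DeLong, because the same
machinery extends to AUPRC. Both validation- and test-split metrics are
emitted, since "internal validation" can mean either.

Attention is aggregated over the **test-split case windows** of each
model (which windows feed the published importance surfaces is unstated;
held-out case windows are the least optimistic choice). The default
β-weighted aggregation is
`S[v,t] = Σ_s β_s[v] α_s[v,t] / Σ_s β_s[v]` — one reading of "temporal
attention averaged with variable-attention weights"; the plain mean over
windows is available by flag. Daily scores are binned to weeks −4…−1
before the window end; weekly binning preserves per-variable means when
T is a multiple of 7. Onset-day summaries use linear-interpolation
quantiles, drop cells with fewer than 20 cases, and compare drugs/sites
with pairwise Welch t tests reported without multiplicity correction.
Repeated-measures ANOVA is the one-way within-subject decomposition with
`F = MS_time/MS_error`; a zero error mean square with a nonzero time
effect is reported as `F = ∞, p = 0` by convention.

## 6. The synthetic generator: what it emulates, and what it does not

`generate_site()` plants the full causal structure the pipeline is meant
to recover, deterministically per seed:

* **Demographics & comorbidities** — age ~ N(60, 15.5²) (years), 58%
  male, ten comorbidities at roughly the pooled prevalences of large
  multicenter AKI cohorts (neoplasm 52%, hypertension 25%, diabetes 16%,
  …).
* **Exposure mix** — acetaminophen 30%, vancomycin 30%, naproxen 15%,
  celecoxib 15%, acyclovir 10%. The published pooled onset profile
  (median 17 d) is a mixture over unprinted per-drug cohort sizes; an
  equal mix pools to ~19 d under the per-drug distributions below, while
  this clinically plausible mix (common analgesics/antibiotics dominate)
  pools to 17 d.
* **Case assignment** — logistic in standardized age, sex and baseline
  SCr (weights 0.5/0.4/0.5 × `confound_strength`), intercept calibrated
  by root-finding so the expected case fraction equals `aki_frac`
  (default 0.12). The default produces a pre-matching age SMD above 0.2 —
  confounding is real, and 0.12 reflects reported incidence of
  drug-induced nephrotoxicity in exposed inpatients (~10–20% for
  vancomycin, lower for the others) while leaving a control pool deep
  enough for 1:3 matching without replacement. (The 8643/31,012 split of
  the published cohort is a *post-matching* ratio, not an exposure-cohort
  prevalence, and is not a valid value for this parameter.)
* **Onset days** — per-drug lognormals parameterised from published
  median/IQR pairs (`sdlog = log(q3/q1)/(2·Φ⁻¹(0.75))`), truncated to
  60 days with `meanlog` recalibrated by root-finding so the truncated
  median equals the configured median (untreated truncation drags the
  23-day acyclovir median to ~18).
* **Trajectories** — irregular lab sampling (per-variable Poisson gaps,
  mean 3–7 days) so forward-fill is genuinely exercised; case SCr ramps
  in the final pre-onset week, is forced to ≥ 2 × ULN on the onset day
  and stays elevated; control and pre-index case SCr are bounded below
  the threshold. Case labs drift linearly over the 28 pre-onset days
  (lymphocytes −1.5 %/wk, albumin −0.12 g/dL/wk, hemoglobin −0.35
  g/dL/wk, urine pH +0.12/wk, prothrombin time +0.5 s/wk); control labs
  are stationary noise around per-patient baselines, the simplest
  reading of flat population curves.
* **Eligibility by construction** — every non-spoiler patient passes all
  inclusion rules (forced pre-index SCr draws at index−50 and index−10
  days); a configurable `spoiler_frac` plants patients who each violate
  exactly one rule, cycling through the three exclusion reasons.

What it does **not** emulate — and hence what green tests do not show
about real data: informative/visit-driven sampling (labs are measured at
random, not because clinicians are worried), measurement error structure
beyond i.i.d. Gaussian noise, care-pathway correlations between drugs,
procedures and diagnoses, competing risks (death, discharge), site-level
coding heterogeneity, and any nonlinearity in the prodromal drift. The
suite demonstrates that the pipeline recovers structure it is pointed at;
it cannot certify performance on hospital EHRs.

## 7. Numerical choices and degenerate inputs

Dates are anchored at a fixed epoch (simulation day 0 = 2015-01-01). Seeds
fan out from the global seed through a fixed integer fold
(`derive_seed()`), so partial reruns of a stage reproduce the full run.
Zero-variance paired differences give p = 1 with a warning; `b + c = 0`
gives p = 1 in McNemar; zero predicted positives give precision 0 with a
warning; all-tie scores give AUROC 0.5; empty matching pools warn and
return empty matchings; single-person groups report SD 0 by convention.
Per-(site, drug) cells with fewer than `min_cases` (default 20) cases are
skipped with a logged reason, matching the practice of suppressing
under-sized cells in published per-site analyses. Problem sizes used by
the test suite and the acceptance script (hundreds to a few thousand
patients per site, ~400 windows per training run) are chosen so the whole
battery runs on one CPU in minutes; they are stated in the tests
themselves.

## 8. Known limitations

The per-drug models share no information across drugs or sites (no
pooling/meta-analysis); calibration of predicted probabilities is not
assessed; the KDIGO urine-output criterion and AKI staging beyond the
doubling rule are out of scope; matching offers no optimal or Mahalanobis
variant; and the attention surface is descriptive — it orders variables
and weeks but is not a causal attribution.
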