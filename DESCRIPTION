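Package: akitrace
Title: Temporal Detection of Drug-Induced Acute Kidney Injury in Multicenter EHR Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for pharmacovigilance of drug-induced acute
    kidney injury (AKI) in observational electronic health records organised as
    an OMOP-CDM-style table subset. Implements serum-creatinine AKI cohort
    phenotyping with a fixed upper-limit-of-normal baseline, 1:3 propensity
    score matching on age, sex and baseline creatinine, candidate-predictor
    selection by paired tests, fill-imputed daily grids windowed into 4-week
    sequences, an interpretable multivariable LSTM with mixed temporal and
    variable attention trained by Adam with early stopping, discrimination
    metrics with bootstrap confidence intervals, attention aggregation into
    temporal feature-importance surfaces, onset-time statistics, and a seeded
    multi-site synthetic EHR generator so the whole pipeline is testable
    without access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
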