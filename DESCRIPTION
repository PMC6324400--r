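Package: icuref
Title: Outcome-Stratified Reference Intervals for ICU Laboratory Values
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparing the distributions of worst first-day
    intensive-care laboratory values against hospital reference intervals
    and across mortality/length-of-stay outcome groups. Implements
    first-stay cohort selection, per-test worst-value extraction over a
    configurable first-day window, five-level outcome stratification
    (survivor length-of-stay quartiles plus ICU death), trimmed central
    95 percent intervals, kernel-density based overlapping coefficients
    (OVL), standardized mean differences (SMD), outcome-proportion
    profiles across the lab-value axis, and a synthetic MIMIC-like
    cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'panel.R'
    'cohort-builder.R'
    'reference-model.R'
    'divergence-stats.R'
    'outcome-profiles.R'
    'pipeline.R'
    'synthetic-cohort.R'
    'run-pipeline.R'
    'zzz.R'
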