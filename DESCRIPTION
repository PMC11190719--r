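Package: rilkinetics
Title: Lymphocyte Depletion Kinetics and Dose-Volume Predictors of
    Radiation-Induced Lymphopenia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling radiation-induced lymphopenia (RIL) from
    longitudinal absolute lymphocyte counts (ALC) and treatment-plan
    dosimetry. Fits per-patient exponential decay curves
    ALC(t) = a*exp(-b*t) + c with quality-control rules, derives the
    percentage ALC loss endpoint from the area under the fitted curve,
    the nadir and CTCAE lymphopenia grade, validates cumulative
    dose-volume-histogram (cDVH) summaries, converts doses to EQD2 and
    computes EDRIC (effective dose to circulating immune cells), and
    provides the downstream association pipeline: univariable R-squared
    screening of dose metrics, ANCOVA comparison of treatment techniques
    adjusted for target volume, Spearman endpoint comparison, principal
    component summaries of collinear dose metrics, and multivariable
    linear models with optimism-corrected R-squared via bootstrap.
    Includes a seeded synthetic cohort generator with stored ground truth
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
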