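Package: pharmacheck
Title: Rule-Based Screening of Electronic Health Records for High-Risk
    Medication Situations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A clinical decision support engine for hospital pharmacists. Scans
    a document-oriented electronic health record store (prescriptions with ATC
    codes, timestamped laboratory results, free-text admission-note problems,
    nursing administration events, demographics) against a configurable book of
    twenty clinical rules covering abnormal laboratory values (including
    Cockcroft-Gault creatinine clearance on the lower of measured and ideal
    body weight, and CKD-EPI eGFR progression), contraindications in clinical
    context, drug-drug interactions and inadequate administration modes.
    Alerts are deduplicated across repeated screening runs; pharmacist
    interventions and prescriber outcomes are tracked in an append-only
    ledger, from which intervention and clinical positive predictive values
    are reported at rule, sub-category and category level. A seeded synthetic
    inpatient-cohort generator with known ground truth supports end-to-end
    validation without any real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
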