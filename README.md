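# pharmacheck

Rule-based screening of electronic health records for high-risk medication
situations, built for hospital clinical pharmacists.

Computerized order entry already shows prescribers pop-up alerts — and
override rates of 60–90 % show how quickly alert fatigue sets in. An
alternative model routes alerts to a clinical pharmacist instead: a
screening engine repeatedly scans every inpatient's record, the pharmacist
filters out futile alerts, and only the clinically relevant minority
reaches the prescriber as a phone call or ward-round suggestion.
`pharmacheck` implements that model end to end:

* a **document data model** for EHR collections (prescriptions with WHO ATC
  codes, timestamped laboratory results, free-text admission notes, nursing
  administration events, demographics) with an NDJSON on-disk format;
* a **rule engine** evaluating twenty clinical rules in four risk
  categories — abnormal laboratory values, contraindications in clinical
  context, drug–drug interactions, inadequate administration modes — via
  staged query primitives (active orders → recent labs / notes →
  projection);
* **renal calculators**: Cockcroft–Gault clearance on the lower of measured
  and Devine ideal body weight (the trigger quantity for the four
  renal-failure rules), CKD-EPI eGFR and its progression between the last
  two measurements,

  `ClCG = (140 − age) · weight · k / S_cr[µmol/L]`, `k = 1.23 (M) / 1.04 (F)`;
* an **alert manager** that deduplicates repeated firings under the
  identity `(patient, rule, trigger-drug set)` and tracks pharmacist
  interventions and prescriber outcomes (accepted only within 24 h) in an
  append-only, replayable ledger;
* an **evaluation module** reporting, at rule / sub-category / category /
  total scope: intervention PPV = interventions ⁄ alerts, clinical PPV with
  pharmacist = accepted ⁄ interventions, clinical PPV without pharmacist =
  accepted ⁄ alerts;
* a **synthetic cohort generator** that emulates an internal-medicine
  census (age median 74, ~13 drugs per patient, stay ~10.5 d) with injected
  risk situations and near-miss controls, providing exact ground truth for
  validation — no real patient data anywhere.

## Worked example

```r
library(pharmacheck)

g <- generate_cohort(cohort_config(n_patients = 40, seed = 7))
g$store
#> <ehr_store>
#>   patients         40 documents
#>   prescriptions    513 documents
#>   labs             414 documents
#>   notes            40 documents
#>   administrations  2 documents

rb <- build_default_rulebook()
cands <- evaluate_all(rb, g$store, g$as_of)
head(candidates_table(cands)[, 1:3], 5)
#>   patient_id                   rule_id     trigger_atc
#> 1      P0002   metformin_renal_failure         A10BA02
#> 2      P0003      aminoglycoside_level         J01GB03
#> 3      P0008             digoxin_level         C01AA05
#> 4      P0012 anticoagulant_duplication B01AF01+B01AF02
#> 5      P0015                   vka_inr         B01AA07
```

The generator injected one situation per rule, and screening finds exactly
those twenty: patient `P0002` is on metformin with a Cockcroft–Gault
clearance ≤ 30 mL/min, `P0012` has two direct oral anticoagulants active
concurrently, and so on. Reconciling against an empty ledger creates the
alerts; the pharmacist's work is then recorded against them:

```r
res <- reconcile(new_alert_ledger(), cands, g$as_of)
nrow(res$new_alerts)
#> [1] 20

led <- record_intervention(res$ledger, "A00001", TRUE, "phone",
                           "2020-04-15T10:30",
                           suggestion = "hold DOAC, reassess renal function")
led <- record_outcome(led, "A00001", "accepted", "2020-04-15T16:00")
build_report(led, rb) |> subset(scope == "total")
#> scope        id        alerts    int    acc     iPPV    cPPV+    cPPV-
#> total        total         20      1      1     5.0%   100.0%     5.0%
```

One of twenty alerts led to an intervention (intervention PPV 5.0 %), which
was accepted within the 24 h window (clinical PPV with pharmacist 100.0 %).
Re-screening the unchanged store only refreshes the existing alerts — a
repetitive situation is counted once.

The context shown with a renal alert:

```r
renal_assessment(80, "male", 150, weight_measured_kg = 90, height_cm = 152,
                 egfr_previous = 50, egfr_latest = 57)
#> <renal_assessment>
#>   creatinine: 150.0 umol/L
#>   weight (measured/ideal/selected): 90.0 / 50.0 / 50.0 kg
#>   ClCG: 24.6 mL/min   eGFR (CKD-EPI): 37.3 mL/min/1.73m2
#>   delta eGFR: +14%
```

A thin command-line front end covers the same pipeline
(`exec/pharmacheck simulate | screen | track | report`), and the default
rulebook ships as an editable YAML config
(`inst/extdata/rulebook-default.yaml`).

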