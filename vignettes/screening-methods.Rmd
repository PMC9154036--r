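---
title: "Screening methods: rules, calculators and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening methods: rules, calculators and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmacheck)
```

## The screening model

`pharmacheck` implements a rule-based clinical decision support engine for
hospital pharmacists. Instead of interrupting prescribers with pop-ups at
order entry, it passively and repeatedly screens a document-oriented EHR
store — prescriptions, laboratory results, free-text admission-note
problems, nursing administration events and demographics — against a book of
twenty clinical rules, each encoding a high-risk medication situation with
the potential to cause a serious adverse drug event. Alerts go to a
pharmacist, who filters out the futile ones before contacting the
prescriber; the package also tracks those interventions and their outcomes
so the yield of every rule can be quantified.

Each rule is an IF–THEN trigger over document predicates, one of four kinds:

* **drug × laboratory value** — a drug set (ATC prefixes and/or substance
  labels) combined with a threshold on the *latest* in-window laboratory
  value. Twelve rules, in three sub-categories: renal failure (threshold on
  computed creatinine clearance, not on any stored result), supratherapeutic
  drug levels (INR, vancomycin, digoxin, aminoglycosides), and other
  abnormal values (hypoglycemia under glucose-lowering therapy, heparin with
  thrombopenia, digoxin with dyskalemia, metformin with hyperlactatemia).
* **drug × problem keyword** — a drug set combined with a French free-text
  keyword in the admission note (anticholinergics with predisposing
  comorbidities, seizure-threshold-lowering drugs with epilepsy,
  NSAID/metamizole with cardiac, renal or ulcer history).
* **therapeutic duplication** — at least two concurrently active
  prescriptions from named classes (two anticoagulants, with the intended
  VKA + heparin bridge excluded; two serotonergic drugs).
* **administration mode** — "never event" checks: two methotrexate doses
  scheduled within 7 days, intravenous potassium chloride faster than
  10 mmol/h or above route-specific concentration limits.

Comparator inclusivity is part of the rule definition and is enforced
literally: `<=`/`>=` thresholds fire *at* the threshold, `>` thresholds do
not. The boundary test suite enumerates every rule at threshold ± ε.

## Query semantics

Screening happens through three staged primitives, mirroring the
aggregation-pipeline style of a document database:

1. `active_prescriptions()` — signed (`CHECKED`) orders whose validity
   interval contains the screening instant. Activity uses the half-open
   interval `[start_at, end_at)`; an absent end is an open order. Draft and
   stopped orders never trigger.
2. `recent_labs()` — laboratory results with a publication date strictly
   within the last 30 days (`as_of − 30 d < published_at ≤ as_of`), newest
   first. Thirty days is the recency horizon for *all* lab-triggered rules
   and can be overridden per rule in the config file.
3. projection into an `alert_candidate` — at most one candidate per patient
   and rule, carrying the matched prescriptions, the triggering evidence and
   the context values a pharmacist needs (previous laboratory values, renal
   assessment, offending combination pairs).

Timestamps are timezone-naive ISO-8601 at minute resolution. Only the most
recent in-window value of an analyte can trigger; older in-window values are
reported as context. A patient missing an input a renal rule needs (no
creatinine in the window, no usable weight, age below 18) is *skipped with a
logged abstention* rather than alerted on missing data — a deliberate
bias toward specificity for a pharmacist-facing tool.

Drug matching folds case and diacritics and stems a trailing `e`, so French
substance spellings ("metformine", "warfarine") match international
nonproprietary names. ATC matching is by prefix: a rule naming `M01A`
matches any NSAID beneath it.

## Renal calculators

The renal rules trigger on Cockcroft–Gault creatinine clearance computed on
the **lowest** of measured and ideal body weight:

* Ideal body weight uses the cm-linearized Devine estimate
  (`50 | 45.5 + 0.9 × (height − 152)` kg), floored at zero. No formula is
  canonical for this step; Devine is the common dosing convention and the
  choice is config-overridable.
* Cockcroft–Gault is evaluated in SI form,
  `ClCG = (140 − age) × weight × k / creatinine[µmol/L]` with `k = 1.23`
  (male) / `1.04` (female). The classic mg/dL `/72` form is algebraically
  identical after unit conversion; a single canonical path avoids double
  rounding. Adult scope only (age ≥ 18).
* CKD-EPI (2009 two-level spline, age decay `0.993^age`, 1.018 female
  coefficient) is computed for display and progression context. The race
  coefficient is not applied, consistent with race-free eGFR reporting; the
  continuity of the spline at the sex-specific knot is property-tested.
* The delta-eGFR context value is the signed percent change between the
  last two stored eGFR results, e.g. `(50, 57) → +14 %`.

All values are carried at full precision and rounded only for display.

## Alert lifecycle and metrics

Repeated screening runs are deduplicated under the identity
`(patient, rule, sorted trigger-drug ATC set)`: a situation still present at
the next run only refreshes its alert, so a repetitive alert is counted
once. Including the drug set in the key means a *new* offending drug for the
same rule re-alerts, which we judged the safer reading of "counted once".
An alert whose trigger clears (order stopped, laboratory back in range) is
resolved; a recurrence afterwards is a new alert. The ledger is an
append-only event log and all state is a pure fold over it, so a written
ledger replays to identical state.

A pharmacist either intervenes (phone or ward round) or rules the alert
futile. An intervention's suggestion counts as **accepted** only if the
change in patient management happened within 24 h of the intervention;
later acceptances are stored as `accepted_late` and excluded from
acceptance counts. The 24 h window is measured from the intervention
itself — the follow-up chart check at 24–72 h is an observation schedule,
not the window. Declined outcomes carry one of three reasons (positive
benefit–risk, unknown, patient discharged).

Three metrics summarize performance at rule, sub-category, category and
total scope:

* intervention PPV = interventions / alerts,
* clinical PPV with pharmacist = accepted changes / interventions,
* clinical PPV without pharmacist = accepted changes / alerts.

Percentages are rounded half-up to 0.1; a zero denominator renders `NA`,
never `0 %`. Pre-rounding the three satisfy
`iPPV × cPPV⁺ / 100 = cPPV⁻`, which the test suite asserts on every report
row. The package always reports *computed* values; it does not attempt to
reconcile rounding artifacts in any externally printed table.

```{r}
report <- build_report(make_reference_ledger(), build_default_rulebook())
report[report$scope != "rule", ]
```

`make_reference_ledger()` is a synthetic ledger whose per-rule counts equal
those observed during the tool's original 132-day deployment (5,466
patients screened, 447 alerts for 383 patients, 90 interventions, 63
accepted); it exists so the reporting arithmetic can be validated end to
end. Only its counts are meaningful — patients and timestamps are
placeholders.

## The synthetic cohort generator

`generate_cohort()` produces the study conditions every engine test runs
under. Its defaults emulate an adult internal-medicine census: age from a
reflected log-normal with median 74 and IQR ≈ 61–82 years; around 13 drug
orders per patient (negative binomial, median 13); length of stay
log-normal with median 10.5 days. Each injected situation is constructed to
satisfy its rule's trigger *exactly* — renal injections work backwards from
a target clearance (uniform 18–28 mL/min below a ≤ 30 threshold) to the
creatinine that produces it on the selected weight. Near-miss controls
violate exactly one condition minimally: clearance one mL/min above
threshold, platelets at 51 G/L, INR 3.9, a methotrexate gap of 8 days, a
potassium chloride rate of exactly 10 mmol/h, a clean admission note for
the keyword rules, a VKA bridged with heparin for the duplication rule.

Background prescriptions come from a curated fifteen-drug formulary chosen
to be disjoint from every rule's drug set, and background laboratory series
stay in safe ranges, so controls cannot alert by accident; about 15 % of
patients additionally carry an *unsigned* (draft) order on a rule drug to
exercise the status filter. Admission notes are French templates free of
all rule keywords unless a keyword rule is injected.

What the generator does **not** emulate: pharmacokinetics or any causal
link between prescriptions and laboratory trajectories, co-occurring risk
situations in one patient, negation or misspelling in notes, and unit
heterogeneity beyond creatinine mg/dL. Passing tests therefore demonstrate
that the engine computes its triggers exactly as specified — not that the
rules are clinically sensitive or specific on real data, where free-text
problems in particular are known to be noisy.

## Validation design

* **Dual-route oracle.** The test suite contains an independent brute-force
  screener: naive nested scans over the raw document tables with inline
  clinical constants, sharing no code with the staged engine. Agreement is
  required on 50 random cohorts of 24–56 patients (mixed injections and
  near-misses).
* **Ground truth.** On the same 50 cohorts the engine must recover the
  injected situations with sensitivity 1.0 and false-positive rate 0.0.
* **Boundaries.** Every comparator is exercised at its threshold and one
  small step to either side.
* **Dedup monotonicity.** Re-screening an unchanged store three times adds
  zero alerts.
* **Census anchors.** Cohort medians (age, drugs per patient, length of
  stay) are checked at n = 1000.

Problem sizes were chosen to keep the full suite around three minutes on a
single core while still covering all twenty rules in every cohort.

## Known limitations and open choices

* The keyword search has no negation detection; "pas d'épilepsie" matches.
  This mirrors the high-sensitivity free-text strategy the screening
  approach accepts, and is the main known source of false positives.
* Drug-level rules require the drug to be active at the screening instant,
  not at the laboratory's publication time; a stopped drug with a still
  recent supratherapeutic level no longer alerts. The simpler activity
  notion was chosen; the alternative is noted as a deviation risk.
* Potassium chloride concentration limits are expressed per route
  continuity (0.08 / 1.00 mmol/mL intermittent / continuous). A
  catheter-based variant (> 40 mmol/L peripheral, > 80 mmol/L central)
  exists in practice and can be configured, but is not the default.
* The strong P-gp/CYP3A4 inducer/inhibitor list shown as context with the
  anticoagulant renal rules ships empty and user-fillable; no authoritative
  machine-readable list was adopted.
* Edoxaban belongs to the DOAC renal-failure rule but not to the
  anticoagulant-duplication classes — fidelity to the deployed rule
  definitions over symmetry.
* The glucose-lowering rule's drug set is the union A10A ∪ A10B (insulins
  plus oral agents), the only internally consistent reading of a rule that
  names both.
* Stopped-then-restarted orders are distinct prescriptions and can produce
  two alerts; order identity, not therapy identity, drives deduplication.
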