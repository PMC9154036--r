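test_that("drug-set matching: ATC prefixes and folded label equality", {
  rx <- rbind(rx_row("RX1", atc_code = "M01AB05", drug_label = "diclofenac"),
              rx_row("RX2", atc_code = "A10BA02", drug_label = "Metformine"),
              rx_row("RX3", atc_code = "C10AA05", drug_label = "atorvastatin"))
  expect_equal(match_drug_set(rx, pc_drug_set(atc = "M01A"))$prescription_id,
               "RX1")
  # French label matches the international substance name after folding
  expect_equal(match_drug_set(rx, pc_drug_set(labels = "metformin"))$prescription_id,
               "RX2")
  expect_equal(nrow(match_drug_set(rx, pc_drug_set(atc = "B01"))), 0)
})

test_that("problem-keyword search folds case and diacritics, no negation", {
  notes <- rbind(note_row(text = "Antécédents : épilepsie connue."),
                 note_row(text = "RAS."))
  hit <- eval_problem_keywords(notes, "épilepsie")
  expect_equal(hit$keyword, "épilepsie")
  expect_equal(hit$note_index, 1)
  expect_gt(hit$offset, 1)
  expect_equal(eval_problem_keywords(note_row(text = "EPILEPSIE"),
                                     "épilepsie")$note_index, 1)
  expect_null(eval_problem_keywords(note_row(text = ""), "épilepsie"))
  # no negation handling, by design
  expect_false(is.null(eval_problem_keywords(
    note_row(text = "pas d'épilepsie"), "épilepsie")))
})

test_that("combination detection honours class exclusions and min count", {
  classes <- pc_anticoagulant_classes()
  excl <- list(c("vka", "lmwh"), c("vka", "ufh"))
  two_doac <- rbind(
    rx_row("RX1", atc_code = "B01AF02", drug_label = "apixaban"),
    rx_row("RX2", atc_code = "B01AF01", drug_label = "rivaroxaban"))
  pairs <- eval_combo(two_doac, classes, excl)
  expect_equal(nrow(pairs), 1)
  expect_setequal(c(pairs$class_1, pairs$class_2), "doac")

  bridged <- rbind(
    rx_row("RX1", atc_code = "B01AA07", drug_label = "acenocoumarol"),
    rx_row("RX2", atc_code = "B01AB05", drug_label = "enoxaparine"))
  expect_equal(nrow(eval_combo(bridged, classes, excl)), 0)

  single <- rx_row("RX1", atc_code = "B01AF02", drug_label = "apixaban")
  expect_equal(nrow(eval_combo(single, classes, excl)), 0)
})

test_that("methotrexate interval check uses an inclusive 7-day bound", {
  ev <- function(days) {
    do.call(rbind, lapply(seq_along(days), function(i) {
      admin_row(scheduled_at = pc_format_ts(
        pc_parse_ts("2020-04-01T09:00") + pc_days(days[[i]])))
    }))
  }
  expect_equal(nrow(eval_mtx_interval(ev(c(0, 7)))), 1)
  expect_equal(nrow(eval_mtx_interval(ev(c(0, 8)))), 0)
  expect_equal(nrow(eval_mtx_interval(ev(c(0, 0)))), 0)  # gap must exceed 0
  expect_equal(nrow(eval_mtx_interval(ev(0))), 0)
  expect_equal(nrow(eval_mtx_interval(ev(c(0, 3, 20)))), 1)
})

test_that("potassium chloride checks are strict and route-aware", {
  kcl <- function(...) rx_row("RX1", atc_code = "B05XA01",
                              drug_label = "chlorure de potassium", ...)
  expect_null(eval_kcl(kcl(route = "iv_continuous", rate_mmol_per_h = 10),
                       "rate"))
  expect_equal(eval_kcl(kcl(route = "iv_continuous", rate_mmol_per_h = 10.1),
                        "rate")$kind, "rate")
  v <- eval_kcl(kcl(route = "iv_intermittent",
                    concentration_mmol_per_ml = 0.09), "concentration")
  expect_equal(v$threshold, 0.08)
  expect_null(eval_kcl(kcl(route = "iv_continuous",
                           concentration_mmol_per_ml = 0.9), "concentration"))
  expect_null(eval_kcl(kcl(route = "oral"), "rate"))  # abstains off-route
})

test_that("renal rule fires on computed clearance with inclusive threshold", {
  rb <- build_default_rulebook()
  rule <- rulebook_rule(rb, "doac_renal_failure")
  # male, 40 y, 60 kg, no height: ClCG = 7380 / creatinine
  store_for <- function(clcg) {
    tiny_store(prescriptions = rx_row("RX1", atc_code = "B01AF02",
                                      drug_label = "apixaban"),
               labs = lab_row(value = 7380 / clcg))
  }
  expect_length(evaluate_rule(rule, store_for(28), AS_OF), 1)
  expect_length(evaluate_rule(rule, store_for(30), AS_OF), 1)    # inclusive
  expect_length(evaluate_rule(rule, store_for(30.1), AS_OF), 0)

  cand <- evaluate_rule(rule, store_for(28), AS_OF)[[1]]
  expect_s3_class(cand, "alert_candidate")
  expect_equal(cand$patient_id, "P1")
  expect_equal(cand$trigger_atc, "B01AF02")
  expect_equal(cand$context$renal_assessment$clcg_ml_min, 28, tolerance = 1e-9)
})

test_that("renal rules abstain (not alert) on missing inputs", {
  rb <- build_default_rulebook()
  rule <- rulebook_rule(rb, "doac_renal_failure")
  apix <- rx_row("RX1", atc_code = "B01AF02", drug_label = "apixaban")

  no_creat <- tiny_store(prescriptions = apix)
  res <- evaluate_rule(rule, no_creat, AS_OF)
  expect_length(res, 0)
  expect_equal(attr(res, "abstentions")$reason, "no creatinine within recency window")

  no_weight <- ehr_store(
    patients = default_patient(weight_kg = NA_real_),
    prescriptions = apix, labs = lab_row(value = 300))
  res <- evaluate_rule(rule, no_weight, AS_OF)
  expect_length(res, 0)
  expect_match(attr(res, "abstentions")$reason, "weight")

  minor <- ehr_store(patients = default_patient(age = 16L),
                     prescriptions = apix, labs = lab_row(value = 300))
  res <- evaluate_rule(rule, minor, AS_OF)
  expect_length(res, 0)
  expect_match(attr(res, "abstentions")$reason, "age")
})

test_that("trigger uses the latest in-window lab only; older go to context", {
  rb <- build_default_rulebook()
  rule <- rulebook_rule(rb, "vka_inr")
  as_of <- pc_parse_ts(AS_OF)
  store <- tiny_store(
    prescriptions = rx_row("RX1", atc_code = "B01AA07",
                           drug_label = "acenocoumarol"),
    labs = rbind(
      lab_row(analyte = "inr", value = 5.2,
              published_at = pc_format_ts(as_of - pc_days(5))),
      lab_row(analyte = "inr", value = 2.1,
              published_at = pc_format_ts(as_of - pc_days(1)))))
  expect_length(evaluate_rule(rule, store, AS_OF), 0)  # latest back in range

  store2 <- tiny_store(
    prescriptions = rx_row("RX1", atc_code = "B01AA07",
                           drug_label = "acenocoumarol"),
    labs = rbind(
      lab_row(analyte = "inr", value = 2.1,
              published_at = pc_format_ts(as_of - pc_days(5))),
      lab_row(analyte = "inr", value = 5.2,
              published_at = pc_format_ts(as_of - pc_days(1)))))
  cand <- evaluate_rule(rule, store2, AS_OF)
  expect_length(cand, 1)
  expect_equal(cand[[1]]$context$previous_labs$inr, 2.1)
})

test_that("PRN prescriptions are excluded from the hypoglycemia rule", {
  rb <- build_default_rulebook()
  rule <- rulebook_rule(rb, "hypoglycemia")
  base_labs <- lab_row(analyte = "glucose", value = 3.5)
  prn <- tiny_store(prescriptions = rx_row("RX1", atc_code = "A10BA02",
                                           drug_label = "metformine",
                                           is_prn = TRUE),
                    labs = base_labs)
  expect_length(evaluate_rule(rule, prn, AS_OF), 0)
  scheduled <- tiny_store(prescriptions = rx_row("RX1", atc_code = "A10BA02",
                                                 drug_label = "metformine"),
                          labs = base_labs)
  expect_length(evaluate_rule(rule, scheduled, AS_OF), 1)
})

test_that("evaluate_all is deterministic, stably ordered, empty on empty", {
  rb <- build_default_rulebook()
  empty <- tiny_store()
  expect_length(evaluate_all(rb, empty, AS_OF), 0)

  g <- generate_cohort(cohort_config(n_patients = 24, seed = 5))
  c1 <- evaluate_all(rb, g$store, g$as_of)
  c2 <- evaluate_all(rb, g$store, g$as_of)
  expect_identical(candidates_table(c1), candidates_table(c2))
  ct <- candidates_table(c1)
  expect_identical(order(ct$patient_id, ct$rule_id), seq_len(nrow(ct)))
})

test_that("disabled rules evaluate to an empty candidate list", {
  rb <- build_default_rulebook()
  rule <- rulebook_rule(rb, "doac_renal_failure")
  rule$enabled <- FALSE
  store <- tiny_store(prescriptions = rx_row("RX1", atc_code = "B01AF02",
                                             drug_label = "apixaban"),
                      labs = lab_row(value = 400))
  expect_length(evaluate_rule(rule, store, AS_OF), 0)
})
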