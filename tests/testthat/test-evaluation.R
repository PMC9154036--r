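test_that("PPV formulas round half-up to 0.1 and handle zero denominators", {
  expect_equal(intervention_ppv(90, 447), 20.1)
  expect_equal(intervention_ppv(20, 71), 28.2)
  expect_true(is.na(intervention_ppv(0, 0)))
  expect_error(intervention_ppv(5, 4))

  expect_equal(clinical_ppv_with(17, 20), 85.0)
  expect_equal(clinical_ppv_with(0, 1), 0.0)
  for (k in c(1, 3, 17)) expect_equal(clinical_ppv_with(k, k), 100.0)
  expect_true(is.na(clinical_ppv_with(0, 0)))

  expect_equal(clinical_ppv_without(16, 64), 25.0)
  expect_equal(clinical_ppv_without(0, 12), 0.0)
  # half-up, not banker's rounding: 0.25% -> 0.3%
  expect_equal(clinical_ppv_without(1, 400), 0.3)
})

test_that("report on an empty ledger is all-zero with NA PPVs", {
  rep <- build_report(new_alert_ledger(), build_default_rulebook())
  expect_equal(sum(rep$n_alerts), 0)
  expect_true(all(is.na(rep$intervention_ppv)))
  expect_equal(nrow(rep[rep$scope == "rule", ]), 20)
  expect_equal(nrow(rep[rep$scope == "category", ]), 4)
})

test_that("rollup conservation: rule counts sum to every parent scope", {
  rep <- build_report(make_reference_ledger(), build_default_rulebook())
  rules <- rep[rep$scope == "rule", ]
  rb <- build_default_rulebook()
  meta <- data.frame(
    rule_id = rulebook_ids(rb),
    category = vapply(rb$rules, `[[`, character(1), "risk_category"),
    subcategory = vapply(rb$rules, `[[`, character(1), "risk_subcategory"),
    stringsAsFactors = FALSE)
  rules <- merge(rules, meta, by.x = "scope_id", by.y = "rule_id")
  for (col in c("n_alerts", "n_interventions", "n_accepted")) {
    for (cat in unique(meta$category)) {
      expect_equal(report_row(rep, "category", cat)[[col]],
                   sum(rules[[col]][rules$category == cat]),
                   label = paste(col, cat))
    }
    for (sub in setdiff(unique(meta$subcategory), "none")) {
      expect_equal(report_row(rep, "subcategory", sub)[[col]],
                   sum(rules[[col]][rules$subcategory == sub]))
    }
    expect_equal(report_row(rep, "total", "total")[[col]], sum(rules[[col]]))
  }
})

test_that("orphan ledger entries are rejected", {
  led <- new_alert_ledger()
  led$entries[[1]] <- list(kind = "alert_new", alert_id = "A00001",
                           dedup_key = "P1|ghost_rule|X", patient_id = "P1",
                           rule_id = "ghost_rule", trigger_atc = "X",
                           at = AS_OF)
  expect_error(build_report(led, build_default_rulebook()), "ghost_rule")
})

test_that("late and pending outcomes are excluded from acceptance counts", {
  store <- tiny_store(prescriptions = rx_row("RX1", atc_code = "B01AF02",
                                             drug_label = "apixaban"),
                      labs = lab_row(value = 300))
  cands <- evaluate_all(build_default_rulebook(), store, AS_OF)
  led <- reconcile(new_alert_ledger(), cands, AS_OF)$ledger
  aid <- ledger_state(led)$alerts$alert_id[[1]]
  led <- record_intervention(led, aid, TRUE, "phone", "2020-04-15T10:00")
  late <- record_outcome(led, aid, "accepted", "2020-04-17T10:00")
  rep <- build_report(late, build_default_rulebook())
  row <- report_row(rep, "rule", "doac_renal_failure")
  expect_equal(row$n_interventions, 1)
  expect_equal(row$n_accepted, 0)
  pending <- build_report(led, build_default_rulebook())
  expect_equal(report_row(pending, "rule", "doac_renal_failure")$n_accepted, 0)
})

test_that("throughput statistics: means, shares, degenerate cases", {
  led <- make_reference_ledger()
  tp <- throughput(led, make_reference_census())
  expect_equal(tp$n_days_screened, 132)
  expect_equal(tp$n_patients_screened, 5466)
  expect_equal(tp$n_alerting_patients, 383)

  one_day <- data.frame(date = as.Date("2020-02-03"), n_screened = 40)
  tp1 <- throughput(new_alert_ledger(), one_day)
  expect_equal(tp1$mean_new_alerts_per_day, 0)
  expect_true(is.na(tp1$sd_new_alerts_per_day))
  expect_error(throughput(new_alert_ledger(), NULL), "at least one")
})
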