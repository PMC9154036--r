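screened_candidates <- function(store, as_of = AS_OF) {
  evaluate_all(build_default_rulebook(), store, as_of)
}

apix_low_clcg <- function() {
  tiny_store(prescriptions = rx_row("RX1", atc_code = "B01AF02",
                                    drug_label = "apixaban"),
             labs = lab_row(value = 300))
}

test_that("a repeated situation is counted once across runs", {
  store <- apix_low_clcg()
  led <- new_alert_ledger()
  r1 <- reconcile(led, screened_candidates(store), "2020-04-15T08:00")
  expect_equal(nrow(r1$new_alerts), 1)
  r2 <- reconcile(r1$ledger, screened_candidates(store, "2020-04-15T14:00"),
                  "2020-04-15T14:00")
  expect_equal(nrow(r2$new_alerts), 0)
  expect_equal(nrow(r2$refreshed), 1)
  st <- ledger_state(r2$ledger)
  expect_equal(nrow(st$alerts), 1)
  expect_equal(pc_format_ts(st$alerts$last_seen_at), "2020-04-15T14:00")
  expect_true(st$alerts$first_fired_at < st$alerts$last_seen_at)
})

test_that("a situation that clears and recurs creates a second alert", {
  store <- apix_low_clcg()
  led <- new_alert_ledger()
  r1 <- reconcile(led, screened_candidates(store), "2020-04-15T08:00")
  # order stopped: trigger cleared -> alert resolved
  stopped <- store
  stopped$prescriptions$status <- "STOPPED"
  r2 <- reconcile(r1$ledger, screened_candidates(stopped), "2020-04-16T08:00")
  expect_equal(r2$resolved, r1$new_alerts$alert_id)
  # new order for the same drug: same dedup key, but previous alert resolved
  r3 <- reconcile(r2$ledger, screened_candidates(store), "2020-04-17T08:00")
  expect_equal(nrow(r3$new_alerts), 1)
  st <- ledger_state(r3$ledger)
  expect_equal(nrow(st$alerts), 2)
  expect_setequal(st$alerts$status, c("resolved", "new"))
})

test_that("a new offending drug for the same rule re-alerts", {
  store <- apix_low_clcg()
  led <- reconcile(new_alert_ledger(), screened_candidates(store),
                   "2020-04-15T08:00")$ledger
  both <- tiny_store(
    prescriptions = rbind(
      rx_row("RX1", atc_code = "B01AF02", drug_label = "apixaban"),
      rx_row("RX2", atc_code = "B01AF01", drug_label = "rivaroxaban")),
    labs = lab_row(value = 300))
  r2 <- reconcile(led, screened_candidates(both), "2020-04-16T08:00")
  # the renal candidate now covers both DOACs: different trigger set -> new
  # alert; the old key clears. The duplication rule also fires.
  expect_gte(nrow(r2$new_alerts), 2)
  expect_true("doac_renal_failure" %in% r2$new_alerts$rule_id)
  expect_true("anticoagulant_duplication" %in% r2$new_alerts$rule_id)
})

test_that("empty candidates on an empty ledger create nothing", {
  r <- reconcile(new_alert_ledger(), list(), AS_OF)
  expect_equal(nrow(r$new_alerts), 0)
  expect_length(r$resolved, 0)
  expect_equal(nrow(ledger_state(r$ledger)$alerts), 0)
})

test_that("every candidate maps to exactly one alert (conservation)", {
  g <- generate_cohort(cohort_config(n_patients = 30, seed = 9))
  cands <- evaluate_all(build_default_rulebook(), g$store, g$as_of)
  r <- reconcile(new_alert_ledger(), cands, g$as_of)
  expect_equal(nrow(r$new_alerts) + nrow(r$refreshed), length(cands))
  r2 <- reconcile(r$ledger, cands, g$as_of + 3600)
  expect_equal(nrow(r2$new_alerts) + nrow(r2$refreshed), length(cands))
})

test_that("intervention records drive the alert state machine", {
  store <- apix_low_clcg()
  led <- reconcile(new_alert_ledger(), screened_candidates(store),
                   AS_OF)$ledger
  aid <- ledger_state(led)$alerts$alert_id[[1]]
  led <- record_intervention(led, aid, TRUE, "phone", "2020-04-15T10:00",
                             suggestion = "switch anticoagulant")
  st <- ledger_state(led)
  expect_equal(st$alerts$status, "under_review")
  expect_equal(st$interventions$outcome, "pending")
  expect_error(record_intervention(led, aid, TRUE, "phone", "2020-04-15T11:00"),
               "already has an intervention")
  expect_error(record_intervention(led, "A99999", TRUE, "phone",
                                   "2020-04-15T11:00"), "unknown alert")

  # pharmacist rules the alert futile: handled without intervention
  led2 <- reconcile(new_alert_ledger(), screened_candidates(store), AS_OF)$ledger
  aid2 <- ledger_state(led2)$alerts$alert_id[[1]]
  led2 <- record_intervention(led2, aid2, FALSE, "ward_round",
                              "2020-04-15T10:00")
  expect_equal(ledger_state(led2)$alerts$status, "handled")
  expect_error(record_outcome(led2, aid2, "accepted", "2020-04-15T12:00"),
               "awaiting an outcome")
})

test_that("acceptance outside the 24 h window is recorded as late", {
  store <- apix_low_clcg()
  base <- reconcile(new_alert_ledger(), screened_candidates(store), AS_OF)$ledger
  aid <- ledger_state(base)$alerts$alert_id[[1]]
  base <- record_intervention(base, aid, TRUE, "phone", "2020-04-15T10:00")

  ontime <- record_outcome(base, aid, "accepted", "2020-04-15T16:00")
  expect_equal(ledger_state(ontime)$interventions$outcome, "accepted")

  late <- record_outcome(base, aid, "accepted", "2020-04-16T16:00")
  expect_equal(ledger_state(late)$interventions$outcome, "accepted_late")

  declined <- record_outcome(base, aid, "declined_benefit_risk",
                             "2020-04-16T09:00")
  expect_equal(ledger_state(declined)$interventions$outcome,
               "declined_benefit_risk")
  expect_error(record_outcome(declined, aid, "accepted", "2020-04-16T10:00"),
               "already has an outcome")
})

test_that("ledger replay after a file round trip reconstructs state", {
  g <- generate_cohort(cohort_config(n_patients = 30, seed = 13))
  cands <- evaluate_all(build_default_rulebook(), g$store, g$as_of)
  led <- reconcile(new_alert_ledger(), cands, g$as_of)$ledger
  st <- ledger_state(led)
  for (i in seq_len(min(3, nrow(st$alerts)))) {
    led <- record_intervention(led, st$alerts$alert_id[[i]], TRUE, "phone",
                               g$as_of + 3600)
  }
  led <- record_outcome(led, st$alerts$alert_id[[1]], "accepted",
                        g$as_of + 7200)
  path <- withr::local_tempfile(fileext = ".ndjson")
  write_ledger(led, path)
  replayed <- read_ledger(path)
  expect_equal(ledger_state(replayed), ledger_state(led))

  tracking <- export_tracking_csv(led)
  expect_equal(nrow(tracking), nrow(ledger_state(led)$alerts))
  expect_true(all(c("alert_id", "rule_id", "patient_id", "intervened",
                    "outcome") %in% names(tracking)))
})
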