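test_that("store construction preserves counts and validates invariants", {
  store <- tiny_store(
    patients = rbind(default_patient("P1"), default_patient("P2", sex = "female")),
    prescriptions = rbind(rx_row("RX1"), rx_row("RX2", status = "DRAFT"),
                          rx_row("RX3", "P2")))
  expect_s3_class(store, "ehr_store")
  expect_equal(nrow(store$patients), 2)
  expect_equal(nrow(store$prescriptions), 3)

  expect_error(tiny_store(prescriptions = rx_row(atc_code = "9XYZ")),
               "ATC grammar", class = "pharmacheck_validation_error")
  expect_error(tiny_store(prescriptions = rx_row(patient_id = "PX")),
               "not in patients", class = "pharmacheck_validation_error")
  expect_error(
    tiny_store(patients = default_patient(age = 150L)),
    "age", class = "pharmacheck_validation_error")
  expect_error(
    tiny_store(prescriptions = rx_row(route = "oral", rate_mmol_per_h = 5)),
    "iv routes", class = "pharmacheck_validation_error")
})

test_that("creatinine reported in mg/dL is converted to umol/L on ingest", {
  store <- tiny_store(labs = lab_row(value = 1, unit = "mg/dL"))
  expect_equal(store$labs$value, 88.4)
  expect_equal(store$labs$unit, "umol/L")
})

test_that("write/load round trip is lossless", {
  store <- tiny_store(
    patients = rbind(default_patient("P1", height_cm = 170),
                     default_patient("P2", sex = "female")),
    prescriptions = rbind(
      rx_row("RX1"), rx_row("RX2", "P2", atc_code = "B05XA01",
                            drug_label = "chlorure de potassium",
                            route = "iv_continuous", rate_mmol_per_h = 8,
                            concentration_mmol_per_ml = 0.5,
                            end_at = "2020-04-20T10:00")),
    labs = rbind(lab_row(), lab_row(analyte = "potassium", value = 4.1)),
    notes = note_row(text = "Antécédents : épilepsie traitée."),
    administrations = admin_row())
  dir <- withr::local_tempdir()
  write_store(store, dir)
  reread <- load_store(dir)
  for (coll in c("patients", "prescriptions", "labs", "notes",
                 "administrations")) {
    expect_equal(reread[[coll]], store[[coll]], label = coll)
  }
})

test_that("malformed store files are rejected with position information", {
  dir <- withr::local_tempdir()
  write_store(tiny_store(prescriptions = rx_row()), dir)
  expect_error(load_store(file.path(dir, "missing")), "not found")

  file.remove(file.path(dir, "labs.ndjson"))
  expect_error(load_store(dir), "missing store file",
               class = "pharmacheck_io_error")

  write_store(tiny_store(), dir)
  f <- file.path(dir, "prescriptions.ndjson")
  writeLines(c(readLines(f), "{not json"), f)
  expect_error(load_store(dir), "line 2.*prescriptions",
               class = "pharmacheck_parse_error")
})

test_that("prescription activity is CHECKED-only on a half-open interval", {
  store <- tiny_store(prescriptions = rbind(
    rx_row("RX1", start_at = "2020-04-14T08:00"),
    rx_row("RX2", status = "DRAFT", start_at = "2020-04-14T08:00"),
    rx_row("RX3", status = "STOPPED", start_at = "2020-04-14T08:00"),
    rx_row("RX4", start_at = AS_OF),
    rx_row("RX5", start_at = "2020-04-01T00:00", end_at = AS_OF),
    rx_row("RX6", start_at = "2020-04-16T00:00")))
  act <- active_prescriptions(store, "P1", AS_OF)
  expect_equal(act$prescription_id, c("RX1", "RX4"))

  unknown <- active_prescriptions(store, "P99", AS_OF)
  expect_equal(nrow(unknown), 0)
  expect_true(isTRUE(attr(unknown, "unknown_patient")))

  # exhaustive boundary enumeration around start/end
  as_of <- pc_parse_ts(AS_OF)
  offsets <- c(-1, 0, 1)  # minutes
  for (ds in offsets) for (de in offsets) {
    start <- as_of + 60 * ds
    end <- as_of + 60 * de + 3600
    st <- tiny_store(prescriptions = rx_row(
      start_at = pc_format_ts(start), end_at = pc_format_ts(end)))
    expect_equal(nrow(active_prescriptions(st, "P1", AS_OF)),
                 as.integer(start <= as_of && as_of < end),
                 label = sprintf("start%+d end%+d", ds, de))
  }
})

test_that("lab recency window is a strict 30-day lookback", {
  as_of <- pc_parse_ts(AS_OF)
  store <- tiny_store(labs = rbind(
    lab_row(value = 90, published_at = pc_format_ts(as_of - pc_days(29))),
    lab_row(value = 95, published_at = pc_format_ts(as_of - pc_days(30))),
    lab_row(value = 99, published_at = pc_format_ts(as_of + pc_days(1)))))
  labs <- recent_labs(store, "P1", "creatinine", 30, AS_OF)
  expect_equal(labs$value, 90)  # 30-days-ago and future results excluded
  expect_equal(nrow(recent_labs(store, "P1", "potassium", 30, AS_OF)), 0)
  expect_error(recent_labs(store, "P1", "sodium", 30, AS_OF),
               class = "pharmacheck_vocab_error")
  expect_error(recent_labs(store, "P1", "creatinine", 0, AS_OF), "window")
})

test_that("last_two_values orders by publication time, keeps the newest two", {
  as_of <- pc_parse_ts(AS_OF)
  store <- tiny_store(labs = rbind(
    lab_row(analyte = "egfr_ckdepi", value = 42,
            published_at = pc_format_ts(as_of - pc_days(3))),
    lab_row(analyte = "egfr_ckdepi", value = 50,
            published_at = pc_format_ts(as_of - pc_days(2))),
    lab_row(analyte = "egfr_ckdepi", value = 57,
            published_at = pc_format_ts(as_of - pc_days(1)))))
  expect_equal(last_two_values(store, "P1", "egfr_ckdepi", AS_OF),
               c(previous = 50, latest = 57))
  one <- tiny_store(labs = lab_row(analyte = "egfr_ckdepi", value = 57))
  expect_equal(last_two_values(one, "P1", "egfr_ckdepi", AS_OF),
               c(previous = NA_real_, latest = 57))
  # publication-time tie broken by insertion order: later document is latest
  tie <- tiny_store(labs = rbind(
    lab_row(analyte = "egfr_ckdepi", value = 50),
    lab_row(analyte = "egfr_ckdepi", value = 57)))
  expect_equal(last_two_values(tie, "P1", "egfr_ckdepi", AS_OF),
               c(previous = 50, latest = 57))
})
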