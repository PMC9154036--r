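# Document data model for the EHR store: patients, prescriptions, laboratory
# results, admission-note problems and nursing administration events, plus the
# staged query primitives rules are evaluated against.

#' Laboratory analyte vocabulary
#'
#' Fixed vocabulary of analytes understood by the screening rules, with the
#' canonical unit each value is stored in. Creatinine reported in mg/dL is
#' converted to umol/L on ingest (see [convert_creatinine()]); all other
#' analytes must already be in their canonical unit.
#'
#' @return A data.frame with columns `analyte` and `unit`.
#' @export
#' @examples
#' analyte_vocabulary()
analyte_vocabulary <- function() {
  data.frame(
    analyte = c("creatinine", "egfr_ckdepi", "potassium", "lactate",
                "platelets", "inr", "glucose", "digoxin_level",
                "vancomycin_level", "gentamicin_level", "tobramycin_level",
                "amikacin_level"),
    unit = c("umol/L", "mL/min/1.73m2", "mmol/L", "mmol/L",
             "G/L", "ratio", "mmol/L", "nmol/L",
             "mg/L", "mg/L", "mg/L", "mg/L"),
    stringsAsFactors = FALSE
  )
}

PC_SEX <- c("male", "female")
PC_STATUS <- c("CHECKED", "DRAFT", "STOPPED")
PC_ROUTE <- c("oral", "iv_intermittent", "iv_continuous", "sc", "other")
PC_NOTE_KIND <- c("admission_note")

# WHO ATC grammar truncated at any level: letter, 2 digits, letter, letter,
# 2 digits.
PC_ATC_RE <- "^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$"

pc_is_atc <- function(x) grepl(PC_ATC_RE, x)

pc_collection_columns <- list(
  patients = c("patient_id", "sex", "age", "height_cm", "weight_kg",
               "ward_id", "admitted_at", "discharged_at"),
  prescriptions = c("prescription_id", "patient_id", "atc_code", "drug_label",
                    "status", "route", "is_prn", "dose_value", "dose_unit",
                    "rate_mmol_per_h", "concentration_mmol_per_ml",
                    "start_at", "end_at", "free_text_comment"),
  labs = c("patient_id", "analyte", "value", "unit", "published_at"),
  notes = c("patient_id", "note_kind", "text", "written_at"),
  administrations = c("patient_id", "atc_code", "scheduled_at", "given")
)

pc_ts_columns <- list(
  patients = c("admitted_at", "discharged_at"),
  prescriptions = c("start_at", "end_at"),
  labs = "published_at",
  notes = "written_at",
  administrations = "scheduled_at"
)

pc_coerce_collection <- function(df, collection) {
  cols <- pc_collection_columns[[collection]]
  if (is.null(df) || nrow(df) == 0) {
    df <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
  }
  missing <- setdiff(cols, names(df))
  for (m in missing) df[[m]] <- NA
  df <- df[, cols, drop = FALSE]
  typed <- c(pc_ts_columns[[collection]],
             switch(collection,
                    patients = c("age", "height_cm", "weight_kg"),
                    prescriptions = c("is_prn", "dose_value", "rate_mmol_per_h",
                                      "concentration_mmol_per_ml"),
                    labs = "value",
                    administrations = "given",
                    character(0)))
  for (cc in setdiff(cols, typed)) df[[cc]] <- as.character(df[[cc]])
  for (tc in pc_ts_columns[[collection]]) df[[tc]] <- pc_parse_ts(df[[tc]])
  if (collection == "patients") {
    df$age <- as.integer(df$age)
    df$height_cm <- as.numeric(df$height_cm)
    df$weight_kg <- as.numeric(df$weight_kg)
  }
  if (collection == "prescriptions") {
    df$is_prn <- as.logical(df$is_prn)
    df$dose_value <- as.numeric(df$dose_value)
    df$rate_mmol_per_h <- as.numeric(df$rate_mmol_per_h)
    df$concentration_mmol_per_ml <- as.numeric(df$concentration_mmol_per_ml)
  }
  if (collection == "labs") df$value <- as.numeric(df$value)
  if (collection == "administrations") df$given <- as.logical(df$given)
  rownames(df) <- NULL
  df
}

pc_validate_collection <- function(df, collection, patient_ids = NULL) {
  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows)) {
      problems <<- c(problems, sprintf("%s document %d: %s", collection, rows, what))
    }
  }
  if (collection == "patients") {
    note(which(is.na(df$patient_id) | df$patient_id == ""), "missing patient_id")
    note(which(duplicated(df$patient_id)), "duplicate patient_id")
    note(which(!df$sex %in% PC_SEX), "sex must be 'male' or 'female'")
    note(which(is.na(df$age) | df$age < 0 | df$age > 130), "age outside [0, 130]")
    note(which(!is.na(df$height_cm) & df$height_cm <= 0), "height_cm not positive")
    note(which(!is.na(df$weight_kg) & df$weight_kg <= 0), "weight_kg not positive")
    note(which(!is.na(df$admitted_at) & !is.na(df$discharged_at) &
                 df$admitted_at > df$discharged_at),
         "admitted_at after discharged_at")
  }
  if (collection == "prescriptions") {
    note(which(is.na(df$prescription_id) | duplicated(df$prescription_id)),
         "missing or duplicate prescription_id")
    note(which(is.na(df$atc_code) | !pc_is_atc(df$atc_code)),
         "atc_code violates ATC grammar")
    note(which(!df$status %in% PC_STATUS),
         sprintf("status not in {%s}", paste(PC_STATUS, collapse = ", ")))
    note(which(!df$route %in% PC_ROUTE), "unknown route")
    note(which(!is.na(df$start_at) & !is.na(df$end_at) & df$start_at > df$end_at),
         "start_at after end_at")
    iv <- df$route %in% c("iv_intermittent", "iv_continuous")
    note(which(!iv & (!is.na(df$rate_mmol_per_h) | !is.na(df$concentration_mmol_per_ml))),
         "rate/concentration only meaningful for iv routes")
  }
  if (collection == "labs") {
    vocab <- analyte_vocabulary()
    note(which(!df$analyte %in% vocab$analyte), "analyte outside vocabulary")
    note(which(is.na(df$value) | df$value < 0), "value missing or negative")
    canonical <- vocab$unit[match(df$analyte, vocab$analyte)]
    bad_unit <- !is.na(canonical) & df$unit != canonical &
      !(df$analyte == "creatinine" & df$unit == "mg/dL")
    note(which(bad_unit), "unit not canonical for analyte")
    note(which(is.na(df$published_at)), "missing published_at")
  }
  if (collection == "notes") {
    note(which(!df$note_kind %in% PC_NOTE_KIND), "unknown note_kind")
    note(which(is.na(df$text)), "text must be non-null (may be empty)")
  }
  if (collection == "administrations") {
    note(which(is.na(df$atc_code) | !pc_is_atc(df$atc_code)),
         "atc_code violates ATC grammar")
    note(which(is.na(df$scheduled_at)), "missing scheduled_at")
  }
  if (!is.null(patient_ids) && collection != "patients") {
    note(which(!df$patient_id %in% patient_ids), "patient_id not in patients")
  }
  problems
}

#' Assemble and validate an EHR document store
#'
#' Bundles the five document collections into a validated store. Every child
#' document must reference a known patient; type invariants (ATC grammar,
#' status/route vocabularies, ordered intervals, canonical lab units) are
#' enforced at construction. Creatinine results supplied in mg/dL are
#' converted to umol/L.
#'
#' @param patients,prescriptions,labs,notes,administrations data.frames (any
#'   may be `NULL` for an empty collection). Timestamp columns accept ISO-8601
#'   strings at minute resolution (`"2020-04-15T08:00"`) or `POSIXct`.
#' @return An object of class `ehr_store`: a list of the five collections.
#' @seealso [load_store()], [write_store()], [active_prescriptions()]
#' @export
ehr_store <- function(patients = NULL, prescriptions = NULL, labs = NULL,
                      notes = NULL, administrations = NULL) {
  store <- list(
    patients = pc_coerce_collection(patients, "patients"),
    prescriptions = pc_coerce_collection(prescriptions, "prescriptions"),
    labs = pc_coerce_collection(labs, "labs"),
    notes = pc_coerce_collection(notes, "notes"),
    administrations = pc_coerce_collection(administrations, "administrations")
  )
  problems <- unlist(lapply(names(store), function(coll) {
    pc_validate_collection(store[[coll]], coll, store$patients$patient_id)
  }))
  if (length(problems)) {
    pc_stop(paste0("invalid EHR documents:\n  ",
                   paste(head(problems, 20L), collapse = "\n  ")),
            "pharmacheck_validation_error")
  }
  mgdl <- store$labs$analyte == "creatinine" & store$labs$unit == "mg/dL"
  if (any(mgdl)) {
    store$labs$value[mgdl] <- convert_creatinine(store$labs$value[mgdl], "mg/dL")
    store$labs$unit[mgdl] <- "umol/L"
  }
  structure(store, class = "ehr_store")
}

#' @export
print.ehr_store <- function(x, ...) {
  cat("<ehr_store>\n")
  for (coll in names(pc_collection_columns)) {
    cat(sprintf("  %-16s %d documents\n", coll, nrow(x[[coll]])))
  }
  invisible(x)
}

PC_SCHEMA_VERSION <- 1L

#' Read an EHR store from a directory of line-delimited document files
#'
#' Each collection lives in `<collection>.ndjson`: a schema-version header
#' line followed by one JSON document per line, UTF-8. All five files must be
#' present; a malformed line is reported with its line number and collection.
#'
#' @param path Directory containing `patients.ndjson`, `prescriptions.ndjson`,
#'   `labs.ndjson`, `notes.ndjson`, `administrations.ndjson`.
#' @return A validated [ehr_store()].
#' @export
load_store <- function(path) {
  if (!dir.exists(path)) pc_stop(sprintf("store directory not found: %s", path))
  collections <- lapply(names(pc_collection_columns), function(coll) {
    file <- file.path(path, paste0(coll, ".ndjson"))
    if (!file.exists(file)) {
      pc_stop(sprintf("missing store file: %s", file), "pharmacheck_io_error")
    }
    lines <- readLines(file, encoding = "UTF-8")
    if (length(lines) == 0) {
      pc_stop(sprintf("%s: empty file, expected schema header", file),
              "pharmacheck_io_error")
    }
    header <- tryCatch(jsonlite::fromJSON(lines[[1]]), error = function(e) NULL)
    if (is.null(header$schema_version) || header$schema_version != PC_SCHEMA_VERSION ||
        !identical(header$collection, coll)) {
      pc_stop(sprintf("%s: bad schema header on line 1", file),
              "pharmacheck_io_error")
    }
    body <- lines[-1]
    body <- body[nzchar(body)]
    docs <- lapply(seq_along(body), function(i) {
      doc <- tryCatch(jsonlite::fromJSON(body[[i]]), error = function(e) NULL)
      if (is.null(doc) || !is.list(doc)) {
        pc_stop(sprintf("malformed document at %s line %d in collection '%s'",
                        file, i + 1L, coll),
                "pharmacheck_parse_error")
      }
      doc[vapply(doc, is.null, logical(1))] <- NA
      as.data.frame(doc, stringsAsFactors = FALSE)
    })
    if (length(docs) == 0) return(NULL)
    cols <- pc_collection_columns[[coll]]
    docs <- lapply(docs, function(d) {
      for (m in setdiff(cols, names(d))) d[[m]] <- NA
      d[, cols, drop = FALSE]
    })
    do.call(rbind, docs)
  })
  names(collections) <- names(pc_collection_columns)
  ehr_store(collections$patients, collections$prescriptions, collections$labs,
            collections$notes, collections$administrations)
}

#' Write an EHR store as line-delimited document files
#'
#' Inverse of [load_store()]; the round trip is lossless at minute timestamp
#' resolution.
#'
#' @param store An [ehr_store()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_store <- function(store, path) {
  stopifnot(inherits(store, "ehr_store"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (coll in names(pc_collection_columns)) {
    df <- store[[coll]]
    for (tc in pc_ts_columns[[coll]]) df[[tc]] <- pc_format_ts(df[[tc]])
    file <- file.path(path, paste0(coll, ".ndjson"))
    header <- jsonlite::toJSON(
      list(schema_version = PC_SCHEMA_VERSION, collection = coll),
      auto_unbox = TRUE)
    lines <- vapply(seq_len(nrow(df)), function(i) {
      doc <- as.list(df[i, , drop = FALSE])
      doc <- doc[!vapply(doc, function(v) is.na(v) || is.null(v), logical(1))]
      as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA))
    }, character(1))
    writeLines(c(as.character(header), lines), file, useBytes = TRUE)
  }
  invisible(path)
}

#' Signed and currently active prescriptions for a patient
#'
#' A prescription is active at `as_of` when its status is `CHECKED` and
#' `start_at <= as_of < end_at` (half-open interval; an absent `end_at` means
#' an open order). Draft and stopped orders never trigger rules.
#'
#' @param store An [ehr_store()].
#' @param patient_id Patient identifier.
#' @param as_of Screening timestamp.
#' @return The matching prescription rows, ordered by `start_at` then
#'   `prescription_id`. For a patient absent from the store, an empty result
#'   carrying attribute `unknown_patient = TRUE` (distinct from an error).
#' @export
active_prescriptions <- function(store, patient_id, as_of) {
  stopifnot(inherits(store, "ehr_store"))
  as_of <- pc_parse_ts(as_of)
  rx <- store$prescriptions
  if (!patient_id %in% store$patients$patient_id) {
    out <- pc_empty_df(rx)
    attr(out, "unknown_patient") <- TRUE
    return(out)
  }
  keep <- rx$patient_id == patient_id &
    rx$status == "CHECKED" &
    !is.na(rx$start_at) & rx$start_at <= as_of &
    (is.na(rx$end_at) | as_of < rx$end_at)
  out <- rx[keep, , drop = FALSE]
  out <- out[order(out$start_at, out$prescription_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recent laboratory results for a patient
#'
#' Returns results published strictly within the recency window:
#' `as_of - window_days < published_at <= as_of`, most recent first. The
#' default window of 30 days is the recency horizon applied to every
#' lab-triggered rule (per-rule override via the rulebook).
#'
#' @param store An [ehr_store()].
#' @param patient_id Patient identifier.
#' @param analyte One of [analyte_vocabulary()]'s codes.
#' @param window_days Positive lookback window in days.
#' @param as_of Screening timestamp.
#' @return Matching lab rows sorted most-recent-first; publication-time ties
#'   are broken by document insertion order (later-inserted first).
#' @export
recent_labs <- function(store, patient_id, analyte, window_days = 30, as_of) {
  stopifnot(inherits(store, "ehr_store"))
  if (!analyte %in% analyte_vocabulary()$analyte) {
    pc_stop(sprintf("unknown analyte '%s'", analyte), "pharmacheck_vocab_error")
  }
  if (!is.numeric(window_days) || window_days <= 0) {
    pc_stop("window_days must be > 0")
  }
  as_of <- pc_parse_ts(as_of)
  labs <- store$labs
  keep <- labs$patient_id == patient_id & labs$analyte == analyte &
    labs$published_at > as_of - pc_days(window_days) &
    labs$published_at <= as_of
  out <- labs[keep, , drop = FALSE]
  ord <- rev(order(as.numeric(out$published_at), seq_len(nrow(out))))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Last two in-window values of an analyte
#'
#' The two most recent results within the recency window, as a
#' `(previous, latest)` pair; either slot is `NA` when fewer than two results
#' exist. Used for progression context such as the change between the last
#' two eGFR measurements.
#'
#' @inheritParams recent_labs
#' @return Named numeric vector `c(previous = , latest = )`.
#' @export
last_two_values <- function(store, patient_id, analyte, as_of, window_days = 30) {
  labs <- recent_labs(store, patient_id, analyte, window_days, as_of)
  c(previous = if (nrow(labs) >= 2) labs$value[[2]] else NA_real_,
    latest = if (nrow(labs) >= 1) labs$value[[1]] else NA_real_)
}
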