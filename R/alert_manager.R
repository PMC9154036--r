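# Alert lifecycle across repeated screening runs: deduplication under a
# (patient, rule, trigger-drug set) identity, and tracking of pharmacist
# interventions and prescriber outcomes in an append-only ledger. The ledger
# is a pure event log; all state is recovered by folding over its entries, so
# replaying a written ledger reconstructs identical state.

PC_OUTCOMES <- c("accepted", "declined_benefit_risk", "declined_unknown",
                 "declined_discharged")
PC_ACCEPT_WINDOW_H <- 24

pc_dedup_key <- function(patient_id, rule_id, trigger_atc) {
  paste(patient_id, rule_id, paste(sort(unique(trigger_atc)), collapse = "+"),
        sep = "|")
}

#' Create an empty alert ledger
#'
#' @return An object of class `alert_ledger` holding an append-only sequence
#'   of entries (screening runs, alerts, refreshes, resolutions,
#'   interventions, outcomes).
#' @seealso [reconcile()], [record_intervention()], [record_outcome()]
#' @export
new_alert_ledger <- function() {
  structure(list(entries = list()), class = "alert_ledger")
}

pc_append_entry <- function(ledger, entry) {
  ledger$entries[[length(ledger$entries) + 1L]] <- entry
  ledger
}

#' Reconstruct ledger state by replaying its entries
#'
#' State is a pure fold over the entry sequence: the same ledger always
#' reconstructs the same state.
#'
#' @param ledger An `alert_ledger`.
#' @return A list with data.frames `alerts` (alert_id, dedup_key, patient_id,
#'   rule_id, trigger_atc, first_fired_at, last_seen_at, status) and
#'   `interventions` (alert_id, intervened, channel, suggestion,
#'   intervened_at, outcome, outcome_at).
#' @export
ledger_state <- function(ledger) {
  stopifnot(inherits(ledger, "alert_ledger"))
  alerts <- list()
  interventions <- list()
  for (e in ledger$entries) {
    switch(e$kind,
      run = NULL,
      alert_new = {
        alerts[[e$alert_id]] <- list(
          alert_id = e$alert_id, dedup_key = e$dedup_key,
          patient_id = e$patient_id, rule_id = e$rule_id,
          trigger_atc = e$trigger_atc,
          first_fired_at = pc_parse_ts(e$at), last_seen_at = pc_parse_ts(e$at),
          status = "new")
      },
      alert_refresh = {
        alerts[[e$alert_id]]$last_seen_at <- pc_parse_ts(e$at)
      },
      alert_resolved = {
        alerts[[e$alert_id]]$status <- "resolved"
      },
      intervention = {
        interventions[[e$alert_id]] <- list(
          alert_id = e$alert_id, intervened = e$intervened,
          channel = e$channel, suggestion = e$suggestion %||% NA_character_,
          intervened_at = pc_parse_ts(e$at),
          outcome = if (e$intervened) "pending" else NA_character_,
          outcome_at = pc_parse_ts(NA_character_))
        alerts[[e$alert_id]]$status <-
          if (e$intervened) "under_review" else "handled"
      },
      outcome = {
        interventions[[e$alert_id]]$outcome <- e$outcome
        interventions[[e$alert_id]]$outcome_at <- pc_parse_ts(e$at)
        alerts[[e$alert_id]]$status <- "handled"
      },
      pc_stop(sprintf("unknown ledger entry kind '%s'", e$kind)))
  }
  col_chr <- function(lst, f) vapply(lst, function(x) as.character(x[[f]] %||% NA), character(1))
  col_lgl <- function(lst, f) vapply(lst, function(x) isTRUE(x[[f]]), logical(1))
  col_ts <- function(lst, f) {
    v <- vapply(lst, function(x) {
      t <- x[[f]]
      if (is.null(t) || length(t) == 0) NA_real_ else as.numeric(t)
    }, numeric(1))
    as.POSIXct(v, origin = "1970-01-01", tz = "UTC")
  }
  alerts <- unname(alerts)
  interventions <- unname(interventions)
  alerts_df <- data.frame(
    alert_id = col_chr(alerts, "alert_id"),
    dedup_key = col_chr(alerts, "dedup_key"),
    patient_id = col_chr(alerts, "patient_id"),
    rule_id = col_chr(alerts, "rule_id"),
    trigger_atc = col_chr(alerts, "trigger_atc"),
    first_fired_at = col_ts(alerts, "first_fired_at"),
    last_seen_at = col_ts(alerts, "last_seen_at"),
    status = col_chr(alerts, "status"),
    stringsAsFactors = FALSE)
  int_df <- data.frame(
    alert_id = col_chr(interventions, "alert_id"),
    intervened = col_lgl(interventions, "intervened"),
    channel = col_chr(interventions, "channel"),
    suggestion = col_chr(interventions, "suggestion"),
    intervened_at = col_ts(interventions, "intervened_at"),
    outcome = col_chr(interventions, "outcome"),
    outcome_at = col_ts(interventions, "outcome_at"),
    stringsAsFactors = FALSE)
  list(alerts = alerts_df, interventions = int_df)
}

#' @export
print.alert_ledger <- function(x, ...) {
  st <- ledger_state(x)
  cat(sprintf("<alert_ledger> %d entries, %d alerts, %d interventions\n",
              length(x$entries), nrow(st$alerts), nrow(st$interventions)))
  invisible(x)
}

#' Reconcile screening candidates with the alert ledger
#'
#' Deduplicates one screening run against history. A candidate whose
#' deduplication key — `(patient, rule, sorted trigger-drug ATC set)` —
#' matches a non-resolved alert only refreshes that alert's `last_seen_at`;
#' it is not counted again. Other candidates create new alerts. Non-resolved
#' alerts whose key no longer fires (trigger cleared: order stopped or lab
#' back in range) are resolved; a situation that later recurs creates a
#' fresh alert.
#'
#' @param ledger An `alert_ledger`.
#' @param candidates Candidate list from [evaluate_all()].
#' @param run_at Timestamp of the screening run.
#' @return A list: updated `ledger`, data.frames `new_alerts` and
#'   `refreshed`, and character vector `resolved` of alert ids.
#' @export
reconcile <- function(ledger, candidates, run_at) {
  stopifnot(inherits(ledger, "alert_ledger"))
  run_at <- pc_parse_ts(run_at)
  st <- ledger_state(ledger)
  open <- st$alerts[st$alerts$status != "resolved", , drop = FALSE]
  ledger <- pc_append_entry(ledger, list(
    kind = "run", at = pc_format_ts(run_at), n_candidates = length(candidates)))
  n_total <- nrow(st$alerts)
  new_rows <- list(); refreshed_rows <- list()
  seen_keys <- character(0)
  for (cand in candidates) {
    key <- pc_dedup_key(cand$patient_id, cand$rule_id, cand$trigger_atc)
    seen_keys <- c(seen_keys, key)
    idx <- match(key, open$dedup_key)
    if (!is.na(idx)) {
      ledger <- pc_append_entry(ledger, list(
        kind = "alert_refresh", alert_id = open$alert_id[[idx]],
        at = pc_format_ts(run_at)))
      refreshed_rows[[length(refreshed_rows) + 1L]] <-
        data.frame(alert_id = open$alert_id[[idx]], dedup_key = key,
                   stringsAsFactors = FALSE)
    } else {
      n_total <- n_total + 1L
      alert_id <- sprintf("A%05d", n_total)
      ledger <- pc_append_entry(ledger, list(
        kind = "alert_new", alert_id = alert_id, dedup_key = key,
        patient_id = cand$patient_id, rule_id = cand$rule_id,
        trigger_atc = paste(cand$trigger_atc, collapse = "+"),
        at = pc_format_ts(run_at)))
      new_rows[[length(new_rows) + 1L]] <-
        data.frame(alert_id = alert_id, dedup_key = key,
                   patient_id = cand$patient_id, rule_id = cand$rule_id,
                   stringsAsFactors = FALSE)
    }
  }
  cleared <- open[!(open$dedup_key %in% seen_keys), , drop = FALSE]
  for (aid in cleared$alert_id) {
    ledger <- pc_append_entry(ledger, list(
      kind = "alert_resolved", alert_id = aid, at = pc_format_ts(run_at)))
  }
  empty_new <- data.frame(alert_id = character(0), dedup_key = character(0),
                          patient_id = character(0), rule_id = character(0),
                          stringsAsFactors = FALSE)
  empty_ref <- data.frame(alert_id = character(0), dedup_key = character(0),
                          stringsAsFactors = FALSE)
  list(ledger = ledger,
       new_alerts = if (length(new_rows)) do.call(rbind, new_rows) else empty_new,
       refreshed = if (length(refreshed_rows)) do.call(rbind, refreshed_rows) else empty_ref,
       resolved = cleared$alert_id)
}

#' Record a pharmacist's assessment of an alert
#'
#' `intervened = TRUE` documents that a suggestion was sent to the prescriber
#' (alert moves to `under_review`, awaiting an outcome); `intervened = FALSE`
#' documents that the pharmacist ruled the alert futile (alert `handled`,
#' no outcome expected). Only one assessment per alert is accepted.
#'
#' @param ledger An `alert_ledger`.
#' @param alert_id Alert identifier.
#' @param intervened Logical.
#' @param channel `"phone"` or `"ward_round"`.
#' @param at Timestamp of the assessment.
#' @param suggestion Free-text suggestion sent to the prescriber.
#' @return The updated ledger.
#' @export
record_intervention <- function(ledger, alert_id, intervened,
                                channel = c("phone", "ward_round"), at,
                                suggestion = NA_character_) {
  channel <- match.arg(channel)
  st <- ledger_state(ledger)
  idx <- match(alert_id, st$alerts$alert_id)
  if (is.na(idx)) pc_stop(sprintf("unknown alert '%s'", alert_id))
  if (st$alerts$status[[idx]] == "resolved") {
    pc_stop(sprintf("alert '%s' is resolved", alert_id))
  }
  if (alert_id %in% st$interventions$alert_id) {
    pc_stop(sprintf("alert '%s' already has an intervention record", alert_id))
  }
  pc_append_entry(ledger, list(
    kind = "intervention", alert_id = alert_id, intervened = isTRUE(intervened),
    channel = channel, suggestion = suggestion,
    at = pc_format_ts(pc_parse_ts(at))))
}

#' Record the prescriber's response to an intervention
#'
#' An accepted suggestion counts only when the change in patient management
#' happened within 24 h of the intervention; a later acceptance is stored as
#' `accepted_late` and excluded from acceptance counts. Declined outcomes
#' carry one of three reasons (benefit-risk judged positive, unknown,
#' patient already discharged).
#'
#' @param ledger An `alert_ledger`.
#' @param alert_id Alert identifier with a pending intervention.
#' @param outcome One of `accepted`, `declined_benefit_risk`,
#'   `declined_unknown`, `declined_discharged`.
#' @param at Timestamp the outcome was established.
#' @return The updated ledger.
#' @export
record_outcome <- function(ledger, alert_id, outcome, at) {
  outcome <- match.arg(outcome, PC_OUTCOMES)
  st <- ledger_state(ledger)
  idx <- match(alert_id, st$interventions$alert_id)
  if (is.na(idx) || !isTRUE(st$interventions$intervened[[idx]])) {
    pc_stop(sprintf("alert '%s' has no intervention awaiting an outcome", alert_id))
  }
  if (!identical(st$interventions$outcome[[idx]], "pending")) {
    pc_stop(sprintf("alert '%s' already has an outcome", alert_id))
  }
  at <- pc_parse_ts(at)
  if (outcome == "accepted") {
    delay_h <- as.numeric(difftime(at, st$interventions$intervened_at[[idx]],
                                   units = "hours"))
    if (delay_h > PC_ACCEPT_WINDOW_H) outcome <- "accepted_late"
  }
  pc_append_entry(ledger, list(
    kind = "outcome", alert_id = alert_id, outcome = outcome,
    at = pc_format_ts(at)))
}

#' Write an alert ledger as an append-only line-delimited file
#'
#' @param ledger An `alert_ledger`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "alert_ledger"))
  header <- jsonlite::toJSON(list(schema_version = PC_SCHEMA_VERSION,
                                  collection = "ledger"), auto_unbox = TRUE)
  lines <- vapply(ledger$entries, function(e) {
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA, null = "null"))
  }, character(1))
  writeLines(c(as.character(header), lines), path, useBytes = TRUE)
  invisible(path)
}

#' Read an alert ledger written by [write_ledger()]
#'
#' @param path Ledger file.
#' @return An `alert_ledger`.
#' @export
read_ledger <- function(path) {
  if (!file.exists(path)) pc_stop(sprintf("ledger file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) pc_stop("empty ledger file, expected schema header")
  header <- tryCatch(jsonlite::fromJSON(lines[[1]]), error = function(e) NULL)
  if (is.null(header$schema_version) || !identical(header$collection, "ledger")) {
    pc_stop(sprintf("%s: bad schema header on line 1", path))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  entries <- lapply(seq_along(body), function(i) {
    tryCatch(jsonlite::fromJSON(body[[i]]), error = function(e) {
      pc_stop(sprintf("malformed ledger entry at line %d", i + 1L),
              "pharmacheck_parse_error")
    })
  })
  structure(list(entries = entries), class = "alert_ledger")
}

#' Export the ledger as a flat pharmacist tracking table
#'
#' One row per alert with its intervention and outcome, the shape of the
#' tracking file a pharmacy team shares during daily screening.
#'
#' @param ledger An `alert_ledger`.
#' @param path Optional CSV output file.
#' @return The tracking data.frame (invisibly when `path` is given).
#' @export
export_tracking_csv <- function(ledger, path = NULL) {
  st <- ledger_state(ledger)
  out <- merge(st$alerts[, c("alert_id", "rule_id", "patient_id",
                             "first_fired_at", "status")],
               st$interventions[, c("alert_id", "intervened", "outcome",
                                    "outcome_at")],
               by = "alert_id", all.x = TRUE)
  out <- out[order(out$alert_id), , drop = FALSE]
  out$first_fired_at <- pc_format_ts(out$first_fired_at)
  out$outcome_at <- pc_format_ts(out$outcome_at)
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, na = "")
    return(invisible(out))
  }
  out
}
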