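# Evaluation of clinical rules against an EHR store. Each rule is evaluated
# patient by patient through the staged query primitives (active
# prescriptions -> recent labs / notes / administrations -> projection into a
# candidate with context values).

#' Match prescriptions against a drug set
#'
#' A prescription matches when its ATC code starts with any of the set's ATC
#' prefixes, or when its normalized label equals one of the set's substance
#' names. Matching is case-insensitive and diacritic-folded, and a trailing
#' "e" is stemmed from labels so French substance spellings compare equal to
#' international names.
#'
#' @param prescriptions Prescription rows (as returned by
#'   [active_prescriptions()]).
#' @param drug_set A list with character vectors `atc` (prefixes) and
#'   `labels` (normalized substance names).
#' @return The matching prescription rows.
#' @export
match_drug_set <- function(prescriptions, drug_set) {
  if (nrow(prescriptions) == 0) return(prescriptions)
  atc <- toupper(prescriptions$atc_code)
  atc_hit <- rep(FALSE, nrow(prescriptions))
  for (prefix in drug_set$atc) {
    atc_hit <- atc_hit | startsWith(atc, prefix)
  }
  label_hit <- pc_normalize_label(prescriptions$drug_label) %in% drug_set$labels
  out <- prescriptions[atc_hit | (label_hit & !is.na(prescriptions$drug_label)), ,
                       drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Search admission notes for problem keywords
#'
#' Case-insensitive, diacritic-folded substring search. No negation
#' detection is attempted: a note reading "pas d'epilepsie" still matches,
#' mirroring the deliberately high-sensitivity / low-specificity free-text
#' strategy this screening approach relies on.
#'
#' @param notes Note rows for one patient.
#' @param keyword_set Non-empty character vector of (French) problem terms.
#' @param note_kind Note kind to search (default `"admission_note"`).
#' @return A list `(keyword, note_index, offset, written_at)` for the first
#'   match, or `NULL` when nothing matches.
#' @export
eval_problem_keywords <- function(notes, keyword_set,
                                  note_kind = "admission_note") {
  stopifnot(length(keyword_set) > 0)
  notes <- notes[notes$note_kind == note_kind & !is.na(notes$text), ,
                 drop = FALSE]
  if (nrow(notes) == 0) return(NULL)
  folded <- pc_fold(notes$text)
  for (kw in keyword_set) {
    fkw <- pc_fold(kw)
    pos <- regexpr(fkw, folded, fixed = TRUE)
    hit <- which(pos > 0)
    if (length(hit)) {
      i <- hit[[1]]
      return(list(keyword = kw, note_index = i, offset = as.integer(pos[[i]]),
                  written_at = notes$written_at[[i]]))
    }
  }
  NULL
}

#' Find offending co-prescription pairs
#'
#' Enumerates unordered pairs of concurrently active prescriptions drawn from
#' the named drug classes, skipping class pairs on the exclusion list (e.g.
#' a vitamin K antagonist bridged with heparin is intended therapy, not
#' duplication).
#'
#' @param prescriptions Active prescription rows for one patient.
#' @param class_sets Named list of drug sets.
#' @param excluded_pairs List of length-2 character vectors of class names.
#' @param min_distinct Minimum number of matching prescriptions (>= 2).
#' @return A data.frame of offending pairs (one row per pair, columns
#'   `prescription_id_1/2`, `class_1/2`); zero rows when none.
#' @export
eval_combo <- function(prescriptions, class_sets, excluded_pairs = list(),
                       min_distinct = 2) {
  stopifnot(min_distinct >= 2)
  empty <- data.frame(prescription_id_1 = character(0),
                      prescription_id_2 = character(0),
                      class_1 = character(0), class_2 = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(prescriptions) < min_distinct) return(empty)
  membership <- lapply(names(class_sets), function(cl) {
    m <- match_drug_set(prescriptions, class_sets[[cl]])
    if (nrow(m)) data.frame(prescription_id = m$prescription_id, class = cl,
                            stringsAsFactors = FALSE)
  })
  membership <- do.call(rbind, membership)
  if (is.null(membership)) return(empty)
  # a prescription belongs to its first matching class
  membership <- membership[!duplicated(membership$prescription_id), , drop = FALSE]
  if (nrow(membership) < min_distinct) return(empty)
  excluded_key <- vapply(excluded_pairs,
                         function(p) paste(sort(p), collapse = "|"), character(1))
  pairs <- utils::combn(seq_len(nrow(membership)), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    key <- paste(sort(c(membership$class[i1], membership$class[i2])),
                 collapse = "|")
    if (key %in% excluded_key) return(NULL)
    data.frame(prescription_id_1 = membership$prescription_id[i1],
               prescription_id_2 = membership$prescription_id[i2],
               class_1 = membership$class[i1], class_2 = membership$class[i2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

#' Find methotrexate doses scheduled too close together
#'
#' Flags pairs of scheduled doses separated by more than 0 and at most
#' `max_gap_days` days (the inclusive 7-day bound encodes the once-weekly
#' oral methotrexate never-event).
#'
#' @param admin_events Administration-event rows already filtered to
#'   methotrexate.
#' @param max_gap_days Inclusive maximum gap in days (default 7).
#' @return data.frame of offending pairs with columns `scheduled_at_1`,
#'   `scheduled_at_2`, `gap_days`.
#' @export
eval_mtx_interval <- function(admin_events, max_gap_days = 7) {
  empty <- data.frame(scheduled_at_1 = pc_parse_ts(character(0)),
                      scheduled_at_2 = pc_parse_ts(character(0)),
                      gap_days = numeric(0))
  if (nrow(admin_events) < 2) return(empty)
  ts <- sort(admin_events$scheduled_at)
  pairs <- utils::combn(seq_along(ts), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    t1 <- ts[[pairs[1, j]]]; t2 <- ts[[pairs[2, j]]]
    gap <- as.numeric(difftime(t2, t1, units = "days"))
    if (gap > 0 && gap <= max_gap_days) {
      data.frame(scheduled_at_1 = t1, scheduled_at_2 = t2, gap_days = gap)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

#' Check an intravenous potassium chloride prescription
#'
#' Rate violation when the prescribed flow rate strictly exceeds 10 mmol/h;
#' concentration violation when an intermittent infusion exceeds 0.08
#' mmol/mL or a continuous infusion exceeds 1.00 mmol/mL (both strict).
#' Non-intravenous potassium prescriptions abstain.
#'
#' @param prescription A single prescription row.
#' @param mode `"rate"` or `"concentration"`.
#' @param rate_threshold,conc_intermittent,conc_continuous Thresholds.
#' @return A list describing the violation (`kind`, `value`, `threshold`),
#'   or `NULL`.
#' @export
eval_kcl <- function(prescription, mode = c("rate", "concentration"),
                     rate_threshold = 10, conc_intermittent = 0.08,
                     conc_continuous = 1.00) {
  mode <- match.arg(mode)
  route <- prescription$route
  if (!route %in% c("iv_intermittent", "iv_continuous")) return(NULL)
  if (mode == "rate") {
    rate <- prescription$rate_mmol_per_h
    if (!is.na(rate) && rate > rate_threshold) {
      return(list(kind = "rate", value = rate, threshold = rate_threshold))
    }
    return(NULL)
  }
  conc <- prescription$concentration_mmol_per_ml
  if (is.na(conc)) return(NULL)
  limit <- if (route == "iv_intermittent") conc_intermittent else conc_continuous
  if (!is.na(limit) && conc > limit) {
    return(list(kind = paste0("concentration_", route), value = conc,
                threshold = limit))
  }
  NULL
}

pc_candidate <- function(rule, patient_id, as_of, snapshot, context,
                         trigger_atc) {
  structure(list(
    rule_id = rule$rule_id,
    patient_id = patient_id,
    as_of = as_of,
    snapshot = snapshot,
    context = context,
    trigger_atc = sort(unique(toupper(trigger_atc)))
  ), class = "alert_candidate")
}

# Context values shared by the renal rules.
pc_renal_context <- function(store, patient, rulebook_modulators, rx_all,
                             window_days, as_of) {
  creat <- recent_labs(store, patient$patient_id, "creatinine", window_days, as_of)
  egfr2 <- last_two_values(store, patient$patient_id, "egfr_ckdepi", as_of,
                           window_days)
  mods <- if (!is.null(rulebook_modulators)) {
    match_drug_set(rx_all, rulebook_modulators)
  }
  list(previous_creatinine = creat$value[-1],
       delta_egfr_pct = delta_egfr_percent(egfr2[["previous"]], egfr2[["latest"]]),
       pgp_cyp3a4_modulators = if (!is.null(mods) && nrow(mods)) mods$drug_label)
}

pc_eval_drug_lab <- function(rule, store, patient, rx, as_of, modulators) {
  t <- rule$trigger
  matched <- match_drug_set(rx, t$drug_set)
  if (t$exclude_prn) matched <- matched[!matched$is_prn, , drop = FALSE]
  if (nrow(matched) == 0) return(NULL)
  window <- t$window_days

  if (t$renal_mode == "clcg_selected_weight") {
    b <- t$branches[[1]]
    if (is.na(patient$age) || patient$age < 18) {
      return(list(abstain = "age below adult scope"))
    }
    creat <- recent_labs(store, patient$patient_id, "creatinine", window, as_of)
    if (nrow(creat) == 0) {
      return(list(abstain = "no creatinine within recency window"))
    }
    ibw <- ideal_body_weight(patient$height_cm, patient$sex)
    dw <- dosing_weight(patient$weight_kg, ibw)
    if (is.na(dw)) {
      return(list(abstain = "no measured or ideal body weight"))
    }
    clcg <- cockcroft_gault(patient$age, dw, creat$value[[1]], patient$sex)
    if (!pc_compare(clcg, b$comparator, b$threshold)) return(NULL)
    egfr2 <- last_two_values(store, patient$patient_id, "egfr_ckdepi", as_of, window)
    assessment <- renal_assessment(
      patient$age, patient$sex, creat$value[[1]],
      weight_measured_kg = patient$weight_kg, height_cm = patient$height_cm,
      egfr_previous = egfr2[["previous"]], egfr_latest = egfr2[["latest"]])
    ctx <- pc_renal_context(store, patient, modulators, rx, window, as_of)
    ctx$renal_assessment <- assessment
    return(pc_candidate(rule, patient$patient_id, as_of,
                        snapshot = list(prescriptions = matched,
                                        labs = creat[1, , drop = FALSE]),
                        context = ctx, trigger_atc = matched$atc_code))
  }

  fired_rx <- list(); fired_labs <- list(); prev <- list()
  for (b in t$branches) {
    bm <- if (is.null(b$drug_set)) matched else match_drug_set(matched, b$drug_set)
    if (nrow(bm) == 0) next
    labs <- recent_labs(store, patient$patient_id, b$analyte, window, as_of)
    if (nrow(labs) == 0) next
    if (pc_compare(labs$value[[1]], b$comparator, b$threshold, b$threshold_high)) {
      fired_rx[[length(fired_rx) + 1L]] <- bm
      fired_labs[[length(fired_labs) + 1L]] <- labs[1, , drop = FALSE]
      prev[[b$analyte]] <- labs$value[-1]
    }
  }
  if (length(fired_rx) == 0) return(NULL)
  rx_snap <- unique(do.call(rbind, fired_rx))
  pc_candidate(rule, patient$patient_id, as_of,
               snapshot = list(prescriptions = rx_snap,
                               labs = do.call(rbind, fired_labs)),
               context = list(previous_labs = prev),
               trigger_atc = rx_snap$atc_code)
}

pc_eval_drug_problem <- function(rule, store, patient, rx, as_of) {
  t <- rule$trigger
  matched <- match_drug_set(rx, t$drug_set)
  if (nrow(matched) == 0) return(NULL)
  notes <- store$notes[store$notes$patient_id == patient$patient_id, ,
                       drop = FALSE]
  hit <- eval_problem_keywords(notes, t$keyword_set, t$note_kind)
  if (is.null(hit)) return(NULL)
  pc_candidate(rule, patient$patient_id, as_of,
               snapshot = list(prescriptions = matched, problem = hit),
               context = list(matched_keyword = hit$keyword,
                              note_written_at = hit$written_at),
               trigger_atc = matched$atc_code)
}

pc_eval_drug_combo <- function(rule, store, patient, rx, as_of) {
  t <- rule$trigger
  pairs <- eval_combo(rx, t$class_sets, t$excluded_pairs, t$min_distinct)
  if (nrow(pairs) == 0) return(NULL)
  involved <- unique(c(pairs$prescription_id_1, pairs$prescription_id_2))
  rx_snap <- rx[rx$prescription_id %in% involved, , drop = FALSE]
  pc_candidate(rule, patient$patient_id, as_of,
               snapshot = list(prescriptions = rx_snap, pairs = pairs),
               context = list(n_pairs = nrow(pairs)),
               trigger_atc = rx_snap$atc_code)
}

pc_eval_admin_mode <- function(rule, store, patient, rx, as_of) {
  t <- rule$trigger
  if (t$mode == "dose_interval") {
    ev <- store$administrations[
      store$administrations$patient_id == patient$patient_id, , drop = FALSE]
    atc_hit <- rep(FALSE, nrow(ev))
    for (prefix in t$drug_set$atc) {
      atc_hit <- atc_hit | startsWith(toupper(ev$atc_code), prefix)
    }
    ev <- ev[atc_hit, , drop = FALSE]
    offending <- eval_mtx_interval(ev, t$max_gap_days)
    if (nrow(offending) == 0) return(NULL)
    return(pc_candidate(rule, patient$patient_id, as_of,
                        snapshot = list(administrations = ev,
                                        offending_pairs = offending),
                        context = list(min_gap_days = min(offending$gap_days)),
                        trigger_atc = ev$atc_code))
  }
  matched <- match_drug_set(rx, t$drug_set)
  if (nrow(matched) == 0) return(NULL)
  violations <- list(); keep <- logical(nrow(matched))
  for (i in seq_len(nrow(matched))) {
    v <- eval_kcl(matched[i, , drop = FALSE], t$mode,
                  rate_threshold = t$rate_threshold,
                  conc_intermittent = t$conc_intermittent,
                  conc_continuous = t$conc_continuous)
    if (!is.null(v)) {
      keep[i] <- TRUE
      violations[[length(violations) + 1L]] <- v
    }
  }
  if (!any(keep)) return(NULL)
  rx_snap <- matched[keep, , drop = FALSE]
  pc_candidate(rule, patient$patient_id, as_of,
               snapshot = list(prescriptions = rx_snap,
                               violations = violations),
               context = list(),
               trigger_atc = rx_snap$atc_code)
}

#' Evaluate one clinical rule against a store
#'
#' Produces at most one alert candidate per patient: the set of that
#' patient's trigger-drug prescriptions satisfying the rule, with its
#' evidence snapshot and context values. Patients missing a demographic or
#' laboratory value required by a renal trigger are skipped and recorded as
#' abstentions (no alert on missing data).
#'
#' @param rule A [clinical_rule()].
#' @param store An [ehr_store()].
#' @param as_of Screening timestamp.
#' @param modulators Optional drug set of strong P-gp/CYP3A4 inducers and
#'   inhibitors used as context by the anticoagulant renal rules.
#' @return List of `alert_candidate` objects ordered by patient id, with an
#'   `abstentions` attribute (data.frame patient_id/rule_id/reason).
#' @export
evaluate_rule <- function(rule, store, as_of, modulators = NULL) {
  stopifnot(inherits(rule, "clinical_rule"), inherits(store, "ehr_store"))
  as_of <- pc_parse_ts(as_of)
  abst <- data.frame(patient_id = character(0), rule_id = character(0),
                     reason = character(0), stringsAsFactors = FALSE)
  if (!rule$enabled) {
    return(structure(list(), abstentions = abst))
  }
  pats <- store$patients
  cands <- list()
  for (i in order(pats$patient_id)) {
    patient <- pats[i, , drop = FALSE]
    rx <- active_prescriptions(store, patient$patient_id, as_of)
    res <- switch(rule$trigger$type,
      drug_lab = pc_eval_drug_lab(rule, store, patient, rx, as_of, modulators),
      drug_problem = pc_eval_drug_problem(rule, store, patient, rx, as_of),
      drug_combo = pc_eval_drug_combo(rule, store, patient, rx, as_of),
      admin_mode = pc_eval_admin_mode(rule, store, patient, rx, as_of),
      pc_stop(sprintf("unknown trigger type '%s'", rule$trigger$type)))
    if (is.null(res)) next
    if (!is.null(res$abstain)) {
      abst <- rbind(abst, data.frame(patient_id = patient$patient_id,
                                     rule_id = rule$rule_id,
                                     reason = res$abstain,
                                     stringsAsFactors = FALSE))
      next
    }
    cands[[length(cands) + 1L]] <- res
  }
  structure(cands, abstentions = abst)
}

#' Screen a store against every enabled rule
#'
#' Union of [evaluate_rule()] over the rulebook, in a stable global order
#' (patient id, then rule id). Deterministic: re-evaluating the same store at
#' the same timestamp yields an identical candidate list.
#'
#' @param rulebook A `rulebook`.
#' @param store An [ehr_store()].
#' @param as_of Screening timestamp.
#' @return List of `alert_candidate` objects with an `abstentions` attribute.
#' @export
evaluate_all <- function(rulebook, store, as_of) {
  stopifnot(inherits(rulebook, "rulebook"))
  as_of <- pc_parse_ts(as_of)
  all_c <- list(); all_a <- list()
  for (rule in rulebook$rules) {
    res <- evaluate_rule(rule, store, as_of,
                         modulators = rulebook$pgp_cyp3a4_modulators)
    all_c <- c(all_c, res)
    all_a[[length(all_a) + 1L]] <- attr(res, "abstentions")
  }
  if (length(all_c)) {
    key <- vapply(all_c, function(x) paste(x$patient_id, x$rule_id), character(1))
    all_c <- all_c[order(key)]
  }
  structure(all_c, abstentions = do.call(rbind, all_a))
}

#' Tabulate alert candidates
#'
#' @param candidates Result of [evaluate_all()] or [evaluate_rule()].
#' @return data.frame with one row per candidate: `patient_id`, `rule_id`,
#'   `trigger_atc` (collapsed with `+`), `as_of`.
#' @export
candidates_table <- function(candidates) {
  if (length(candidates) == 0) {
    return(data.frame(patient_id = character(0), rule_id = character(0),
                      trigger_atc = character(0),
                      as_of = pc_parse_ts(character(0)),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    patient_id = vapply(candidates, `[[`, character(1), "patient_id"),
    rule_id = vapply(candidates, `[[`, character(1), "rule_id"),
    trigger_atc = vapply(candidates, function(x) {
      paste(x$trigger_atc, collapse = "+")
    }, character(1)),
    as_of = pc_parse_ts(vapply(candidates, function(x) pc_format_ts(x$as_of),
                               character(1))),
    stringsAsFactors = FALSE
  )
}
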