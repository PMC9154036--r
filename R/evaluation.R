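# Performance metrics: the three positive predictive values and the rollup
# report at rule, sub-category, category and total scope, plus screening
# throughput statistics.

pc_ppv <- function(numerator, denominator) {
  if (denominator == 0) return(NA_real_)
  round_half_up(100 * numerator / denominator, 1)
}

#' Intervention positive predictive value
#'
#' Share of fired alerts that led to a pharmacist intervention:
#' `100 * n_interventions / n_alerts`, rounded half-up to 0.1. The alert
#' specificity as experienced by the pharmacist.
#'
#' @param n_interventions,n_alerts Counts with
#'   `0 <= n_interventions <= n_alerts`.
#' @return Percent, or `NA_real_` when no alerts fired.
#' @export
#' @examples
#' intervention_ppv(90, 447)  # 20.1
intervention_ppv <- function(n_interventions, n_alerts) {
  if (n_interventions > n_alerts || n_interventions < 0) {
    pc_stop("need 0 <= n_interventions <= n_alerts")
  }
  pc_ppv(n_interventions, n_alerts)
}

#' Clinical positive predictive value with a pharmacist filter
#'
#' Share of pharmacist interventions accepted by the prescriber (a change in
#' patient management within 24 h): `100 * n_accepted / n_interventions`.
#'
#' @param n_accepted,n_interventions Counts with
#'   `0 <= n_accepted <= n_interventions`.
#' @return Percent, or `NA_real_` when there were no interventions.
#' @export
clinical_ppv_with <- function(n_accepted, n_interventions) {
  if (n_accepted > n_interventions || n_accepted < 0) {
    pc_stop("need 0 <= n_accepted <= n_interventions")
  }
  pc_ppv(n_accepted, n_interventions)
}

#' Clinical positive predictive value without a pharmacist filter
#'
#' Hypothetical yield had every alert gone straight to the prescriber:
#' `100 * n_accepted / n_alerts`. Pre-rounding, the three measures satisfy
#' `intervention_ppv * clinical_ppv_with / 100 = clinical_ppv_without`.
#'
#' @param n_accepted,n_alerts Counts with `0 <= n_accepted <= n_alerts`.
#' @return Percent, or `NA_real_` when no alerts fired.
#' @export
clinical_ppv_without <- function(n_accepted, n_alerts) {
  if (n_accepted > n_alerts || n_accepted < 0) {
    pc_stop("need 0 <= n_accepted <= n_alerts")
  }
  pc_ppv(n_accepted, n_alerts)
}

#' Build the performance rollup report
#'
#' Counts alerts, interventions and accepted outcomes per rule from the
#' ledger and rolls them up to sub-category (for abnormal-laboratory rules),
#' category and total scope, attaching the three PPVs at every scope.
#' Outcomes recorded as `accepted_late` or still `pending` are not counted
#' as accepted. Ledger entries referencing a rule absent from the rulebook
#' are an error.
#'
#' @param ledger An `alert_ledger`.
#' @param rulebook The `rulebook` the alerts were screened with.
#' @return A data.frame of class `performance_report` with columns `scope`
#'   (`rule`, `subcategory`, `category`, `total`), `scope_id`, `n_alerts`,
#'   `n_interventions`, `n_accepted`, `intervention_ppv`,
#'   `clinical_ppv_with`, `clinical_ppv_without` (percent, `NA` when the
#'   denominator is zero).
#' @export
build_report <- function(ledger, rulebook) {
  stopifnot(inherits(ledger, "alert_ledger"), inherits(rulebook, "rulebook"))
  st <- ledger_state(ledger)
  ids <- rulebook_ids(rulebook)
  orphans <- setdiff(unique(st$alerts$rule_id), ids)
  if (length(orphans)) {
    pc_stop(sprintf("ledger references rules absent from the rulebook: %s",
                    paste(orphans, collapse = ", ")))
  }
  merged <- merge(st$alerts[, c("alert_id", "rule_id")],
                  st$interventions[, c("alert_id", "intervened", "outcome")],
                  by = "alert_id", all.x = TRUE)
  per_rule <- lapply(rulebook$rules, function(r) {
    rows <- merged[merged$rule_id == r$rule_id, , drop = FALSE]
    data.frame(
      rule_id = r$rule_id,
      risk_category = r$risk_category,
      risk_subcategory = r$risk_subcategory,
      n_alerts = nrow(rows),
      n_interventions = sum(rows$intervened %in% TRUE),
      n_accepted = sum(rows$outcome %in% "accepted"),
      stringsAsFactors = FALSE)
  })
  per_rule <- do.call(rbind, per_rule)
  make_row <- function(scope, scope_id, n_a, n_i, n_acc) {
    data.frame(scope = scope, scope_id = scope_id, n_alerts = n_a,
               n_interventions = n_i, n_accepted = n_acc,
               intervention_ppv = intervention_ppv(n_i, n_a),
               clinical_ppv_with = clinical_ppv_with(n_acc, n_i),
               clinical_ppv_without = clinical_ppv_without(n_acc, n_a),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(per_rule)), function(i) {
    make_row("rule", per_rule$rule_id[[i]], per_rule$n_alerts[[i]],
             per_rule$n_interventions[[i]], per_rule$n_accepted[[i]])
  })
  for (sub in setdiff(PC_RISK_SUBCATEGORIES, "none")) {
    sel <- per_rule$risk_subcategory == sub
    rows[[length(rows) + 1L]] <- make_row(
      "subcategory", sub, sum(per_rule$n_alerts[sel]),
      sum(per_rule$n_interventions[sel]), sum(per_rule$n_accepted[sel]))
  }
  for (cat in PC_RISK_CATEGORIES) {
    sel <- per_rule$risk_category == cat
    rows[[length(rows) + 1L]] <- make_row(
      "category", cat, sum(per_rule$n_alerts[sel]),
      sum(per_rule$n_interventions[sel]), sum(per_rule$n_accepted[sel]))
  }
  rows[[length(rows) + 1L]] <- make_row(
    "total", "total", sum(per_rule$n_alerts),
    sum(per_rule$n_interventions), sum(per_rule$n_accepted))
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  class(report) <- c("performance_report", "data.frame")
  report
}

#' Extract one row of a performance report
#'
#' @param report A `performance_report`.
#' @param scope,scope_id Row selector.
#' @return The selected single row.
#' @export
report_row <- function(report, scope, scope_id) {
  out <- report[report$scope == scope & report$scope_id == scope_id, ,
                drop = FALSE]
  if (nrow(out) != 1) {
    pc_stop(sprintf("no unique report row for %s/%s", scope, scope_id))
  }
  out
}

#' @export
print.performance_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.1f%%", v))
  cat(sprintf("%-12s %-28s %8s %6s %6s %8s %8s %8s\n", "scope", "id",
              "alerts", "int", "acc", "iPPV", "cPPV+", "cPPV-"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-12s %-28s %8d %6d %6d %8s %8s %8s\n",
                x$scope[[i]], x$scope_id[[i]], x$n_alerts[[i]],
                x$n_interventions[[i]], x$n_accepted[[i]],
                fmt(x$intervention_ppv[[i]]), fmt(x$clinical_ppv_with[[i]]),
                fmt(x$clinical_ppv_without[[i]])))
  }
  invisible(x)
}

#' Write a performance report to CSV
#'
#' @param report A `performance_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Screening throughput statistics
#'
#' Mean and standard deviation of newly created alerts per screening day,
#' and the share of screened patients with at least one alert.
#'
#' @param ledger An `alert_ledger`.
#' @param census A data.frame with one row per screening day: columns `date`
#'   (`Date` or parseable string) and `n_screened` (patients screened that
#'   day, counted once on their first screening day).
#' @return A list of class `throughput_stats`: `n_days_screened`,
#'   `n_patients_screened`, `n_alerting_patients`,
#'   `mean_new_alerts_per_day`, `sd_new_alerts_per_day` (`NA` for a single
#'   day), `pct_patients_alerting` (half-up, 0.1 precision).
#' @export
throughput <- function(ledger, census) {
  stopifnot(inherits(ledger, "alert_ledger"))
  if (is.null(census) || nrow(census) == 0) {
    pc_stop("census must cover at least one screening day")
  }
  census$date <- as.Date(census$date)
  st <- ledger_state(ledger)
  alert_days <- as.Date(pc_format_ts(st$alerts$first_fired_at))
  daily <- vapply(census$date, function(d) sum(alert_days == d), numeric(1))
  n_screened <- sum(census$n_screened)
  n_alerting <- length(unique(st$alerts$patient_id))
  if (n_alerting > n_screened) {
    pc_stop("more alerting patients than screened patients in census")
  }
  structure(list(
    n_days_screened = nrow(census),
    n_patients_screened = n_screened,
    n_alerting_patients = n_alerting,
    mean_new_alerts_per_day = round_half_up(mean(daily), 1),
    sd_new_alerts_per_day = round_half_up(stats::sd(daily), 1),
    pct_patients_alerting = round_half_up(100 * n_alerting / n_screened, 1)
  ), class = "throughput_stats")
}

#' @export
print.throughput_stats <- function(x, ...) {
  cat("<throughput_stats>\n")
  cat(sprintf("  %d patients screened over %d days; %d alerting (%.1f%%)\n",
              x$n_patients_screened, x$n_days_screened, x$n_alerting_patients,
              x$pct_patients_alerting))
  cat(sprintf("  new alerts per day: %.1f +/- %s\n", x$mean_new_alerts_per_day,
              if (is.na(x$sd_new_alerts_per_day)) "NA"
              else sprintf("%.1f", x$sd_new_alerts_per_day)))
  invisible(x)
}
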