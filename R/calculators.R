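# Renal-function and body-weight computations used both as rule triggers and
# as decision-support context values.

#' Ideal body weight (Devine, cm-linearized)
#'
#' `50 + 0.9 * (height_cm - 152)` kg for males and `45.5 + 0.9 *
#' (height_cm - 152)` kg for females, floored at 0 for very short statures.
#'
#' @param height_cm Height in cm (> 0); `NA` yields an absent result so the
#'   renal assessment can fall back to measured weight.
#' @param sex `"male"` or `"female"`.
#' @return Ideal body weight in kg, or `NA_real_` when height is missing.
#' @export
#' @examples
#' ideal_body_weight(152, "male")    # 50
#' ideal_body_weight(152, "female")  # 45.5
ideal_body_weight <- function(height_cm, sex) {
  sex <- match.arg(sex, PC_SEX)
  if (is.na(height_cm)) return(NA_real_)
  if (height_cm <= 0) pc_stop("height_cm must be > 0")
  base <- if (sex == "male") 50 else 45.5
  max(0, base + 0.9 * (height_cm - 152))
}

#' Dosing weight: the lower of measured and ideal body weight
#'
#' Renal rules estimate creatinine clearance on the lowest available body
#' weight; with only one weight present that one is used, and with neither
#' the result is absent (renal rules then abstain for the patient).
#'
#' @param weight_measured_kg,weight_ideal_kg Weights in kg, either may be `NA`.
#' @return The minimum of the present values, or `NA_real_`.
#' @export
dosing_weight <- function(weight_measured_kg, weight_ideal_kg) {
  w <- c(weight_measured_kg, weight_ideal_kg)
  w <- w[!is.na(w)]
  if (length(w) == 0) return(NA_real_)
  min(w)
}

#' Cockcroft-Gault creatinine clearance (SI units)
#'
#' `ClCG = (140 - age) * weight * k / creatinine` with creatinine in umol/L
#' and `k = 1.23` (male) or `1.04` (female). This SI form is algebraically
#' the classic `/72` mg/dL form after unit conversion; one canonical path
#' avoids double rounding. Values are floored at 0 (ages above 140 would
#' otherwise go negative). Adult internal-medicine scope: ages below 18 are
#' refused.
#'
#' @param age_years Age in whole years, >= 18.
#' @param weight_kg Body weight in kg (> 0); use [dosing_weight()] for the
#'   trigger quantity.
#' @param creatinine_umol_l Serum creatinine in umol/L (> 0).
#' @param sex `"male"` or `"female"`.
#' @return Estimated creatinine clearance in mL/min.
#' @export
#' @examples
#' cockcroft_gault(80, 60, 150, "male")  # 29.52, below a <= 30 trigger
cockcroft_gault <- function(age_years, weight_kg, creatinine_umol_l, sex) {
  sex <- match.arg(sex, PC_SEX)
  if (is.na(age_years) || age_years < 18) {
    pc_stop("Cockcroft-Gault is applied to adults only (age >= 18)",
            "pharmacheck_scope_error")
  }
  if (is.na(weight_kg) || weight_kg <= 0) pc_stop("weight_kg must be > 0")
  if (is.na(creatinine_umol_l) || creatinine_umol_l <= 0) {
    pc_stop("creatinine_umol_l must be > 0")
  }
  k <- if (sex == "male") 1.23 else 1.04
  max(0, (140 - age_years) * weight_kg * k / creatinine_umol_l)
}

#' CKD-EPI 2009 estimated glomerular filtration rate
#'
#' Two-level spline in standardized creatinine (converted to mg/dL by
#' dividing by 88.4) with sex-specific knot `kappa` (0.7 female, 0.9 male)
#' and exponent `alpha` (-0.329 female, -0.411 male), age decay `0.993^age`,
#' and the 1.018 female coefficient. The race coefficient of the original
#' publication is deliberately not applied (race-free reporting).
#'
#' @inheritParams cockcroft_gault
#' @return eGFR in mL/min/1.73 m^2.
#' @export
ckd_epi <- function(creatinine_umol_l, age_years, sex) {
  sex <- match.arg(sex, PC_SEX)
  if (is.na(age_years) || age_years < 18) {
    pc_stop("CKD-EPI is applied to adults only (age >= 18)",
            "pharmacheck_scope_error")
  }
  if (is.na(creatinine_umol_l) || creatinine_umol_l <= 0) {
    pc_stop("creatinine_umol_l must be > 0")
  }
  scr <- creatinine_umol_l / 88.4
  kappa <- if (sex == "female") 0.7 else 0.9
  alpha <- if (sex == "female") -0.329 else -0.411
  141 * min(scr / kappa, 1)^alpha * max(scr / kappa, 1)^-1.209 *
    0.993^age_years * (if (sex == "female") 1.018 else 1)
}

#' Percent change between the last two eGFR measurements
#'
#' Signed progression of renal function: `100 * (latest - previous) /
#' previous`. Displayed alongside renal alerts so a pharmacist can see
#' whether function is deteriorating or recovering.
#'
#' @param previous,latest eGFR values; `previous` must be > 0 for a defined
#'   result (otherwise `NA_real_` with a warning).
#' @return Percent change, signed.
#' @export
#' @examples
#' delta_egfr_percent(50, 57)   # +14
#' delta_egfr_percent(50, 108)  # +116
delta_egfr_percent <- function(previous, latest) {
  if (is.na(previous) || is.na(latest)) return(NA_real_)
  if (previous <= 0) {
    warning("previous eGFR must be > 0; progression undefined")
    return(NA_real_)
  }
  100 * (latest - previous) / previous
}

#' Convert a creatinine result to umol/L
#'
#' @param value Creatinine value.
#' @param unit `"umol/L"` (passthrough) or `"mg/dL"` (multiplied by 88.4).
#' @return Creatinine in umol/L.
#' @export
convert_creatinine <- function(value, unit) {
  if (unit %in% c("umol/L", "µmol/L")) return(value)
  if (unit == "mg/dL") return(value * 88.4)
  pc_stop(sprintf("unknown creatinine unit '%s'", unit), "pharmacheck_vocab_error")
}

#' Full renal assessment for one patient
#'
#' Bundles the quantities displayed with renal alerts: the selected (lowest)
#' body weight, Cockcroft-Gault clearance on that weight, CKD-EPI eGFR, and
#' the progression between the last two stored eGFR values when available.
#'
#' @param age_years,sex,creatinine_umol_l As for [cockcroft_gault()].
#' @param weight_measured_kg Measured weight in kg (may be `NA`).
#' @param height_cm Height in cm (may be `NA`; ideal weight is then absent).
#' @param egfr_previous,egfr_latest Optional last two stored eGFR values.
#' @return An object of class `renal_assessment` (a named list); `clcg_ml_min`
#'   is `NA` when no weight is available.
#' @export
renal_assessment <- function(age_years, sex, creatinine_umol_l,
                             weight_measured_kg = NA_real_, height_cm = NA_real_,
                             egfr_previous = NA_real_, egfr_latest = NA_real_) {
  ibw <- ideal_body_weight(height_cm, sex)
  selected <- dosing_weight(weight_measured_kg, ibw)
  clcg <- if (is.na(selected)) NA_real_ else {
    cockcroft_gault(age_years, selected, creatinine_umol_l, sex)
  }
  structure(list(
    creatinine_umol_l = creatinine_umol_l,
    weight_measured_kg = weight_measured_kg,
    weight_ideal_kg = ibw,
    weight_selected_kg = selected,
    clcg_ml_min = clcg,
    egfr_ml_min_173 = ckd_epi(creatinine_umol_l, age_years, sex),
    delta_egfr_pct = delta_egfr_percent(egfr_previous, egfr_latest)
  ), class = "renal_assessment")
}

#' @export
print.renal_assessment <- function(x, ...) {
  cat("<renal_assessment>\n")
  cat(sprintf("  creatinine: %.1f umol/L\n", x$creatinine_umol_l))
  cat(sprintf("  weight (measured/ideal/selected): %.1f / %.1f / %.1f kg\n",
              x$weight_measured_kg, x$weight_ideal_kg, x$weight_selected_kg))
  cat(sprintf("  ClCG: %.1f mL/min   eGFR (CKD-EPI): %.1f mL/min/1.73m2\n",
              x$clcg_ml_min, x$egfr_ml_min_173))
  if (!is.na(x$delta_egfr_pct)) {
    cat(sprintf("  delta eGFR: %+.0f%%\n", x$delta_egfr_pct))
  }
  invisible(x)
}
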