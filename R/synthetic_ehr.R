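# Seeded generator of synthetic internal-medicine inpatient cohorts with
# known injected high-risk situations and near-miss controls. Background
# medication is drawn from a curated ATC list disjoint from every rule's
# drug set, so control patients cannot alert by accident; background
# laboratory series stay inside safe ranges. The generator is the ground
# truth used to validate the screening engine end to end.

# Curated background formulary: common internal-medicine drugs outside all
# rule drug sets (no anticoagulants, antidiabetics, NSAIDs, psychotropics,
# antihistamines, beta-lactams/quinolones, digoxin...).
pc_background_formulary <- function() {
  data.frame(
    atc_code = c("N02BE01", "A02BC02", "C08CA01", "C10AA05", "C07AB07",
                 "H03AA01", "A06AD15", "C09AA03", "R03AC02", "C03CA01",
                 "B03BA01", "C09AA02", "C07AB02", "C10AA01", "A02BC05"),
    drug_label = c("paracetamol", "pantoprazole", "amlodipine", "atorvastatin",
                   "bisoprolol", "levothyroxine", "macrogol", "lisinopril",
                   "salbutamol", "furosemide", "cyanocobalamin", "enalapril",
                   "metoprolol", "simvastatin", "esomeprazole"),
    stringsAsFactors = FALSE
  )
}

pc_clean_note_templates <- function() {
  c("Patient admis pour pneumonie communautaire. Antécédents : hypertension artérielle, dyslipidémie.",
    "Admission pour érysipèle du membre inférieur droit. Antécédents : BPCO, tabagisme ancien.",
    "Hospitalisation pour douleur thoracique atypique. Antécédents : hypothyroïdie substituée.",
    "Admis pour baisse de l'état général et déshydratation. Antécédents : hypertension artérielle.")
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate an adult internal-medicine census: age drawn from a
#' left-skewed (reflected log-normal) distribution with median 74 and
#' interquartile range 61-82 years; around 13 drug orders per patient
#' (negative binomial, median 13); length of stay log-normal with median
#' 10.5 days. One situation of every rule is injected by default, and a
#' quarter of the cohort carries near-miss controls placed just outside the
#' trigger thresholds.
#'
#' @param n_patients Cohort size.
#' @param injections Named integer vector: situations to inject per rule id.
#'   Defaults to one per rule of the default rulebook.
#' @param near_miss_fraction Fraction of the cohort turned into near-miss
#'   controls (rules cycled; capped by the patients left after injections).
#' @param seed Integer seed fixing all randomness.
#' @param as_of Screening timestamp the cohort is built around.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 60, injections = NULL,
                          near_miss_fraction = 0.25, seed = 1,
                          as_of = "2020-04-15T08:00") {
  ids <- rulebook_ids(build_default_rulebook())
  if (is.null(injections)) {
    injections <- setNames(rep(1L, length(ids)), ids)
  }
  if (is.null(names(injections)) || !all(names(injections) %in% ids)) {
    pc_stop("injections must be named by rule ids of the default rulebook")
  }
  if (sum(injections) > n_patients) {
    pc_stop("infeasible config: more injections than patients")
  }
  structure(list(n_patients = n_patients, injections = injections,
                 near_miss_fraction = near_miss_fraction, seed = seed,
                 as_of = as_of), class = "cohort_config")
}

pc_sample_age <- function(n) {
  # reflected log-normal: median 74, IQR ~61-82, long left tail
  age <- round(94.8 - rlnorm(n, meanlog = log(20.8), sdlog = 0.72))
  pmin(pmax(age, 18), 105)
}

# Creatinine (umol/L) that yields the requested Cockcroft-Gault clearance on
# the selected (lowest) weight; the generator works backwards from clearance
# so renal injections hit their trigger exactly.
pc_creatinine_for_clcg <- function(target_clcg, age, weight_selected, sex) {
  k <- if (sex == "male") 1.23 else 1.04
  (140 - age) * weight_selected * k / target_clcg
}

# Specification of the injected situation per rule: drugs to add, lab
# excursions, note keywords, administration events. `near` flips each
# situation to its minimal near-miss (one condition just outside threshold).
pc_injection_plan <- function(rule_id, near) {
  drug <- function(atc, label, route = "oral", rate = NA, conc = NA,
                   prn = FALSE) {
    list(atc = atc, label = label, route = route, rate = rate, conc = conc,
         prn = prn)
  }
  lab <- function(analyte, value) list(analyte = analyte, value = value)
  switch(rule_id,
    doac_renal_failure = list(
      drugs = list(drug("B01AF02", "apixaban")),
      target_clcg = if (near) 31 else runif(1, 18, 28)),
    colchicine_renal_failure = list(
      drugs = list(drug("M04AC01", "colchicine")),
      target_clcg = if (near) 31 else runif(1, 18, 28)),
    morphine_renal_failure = list(
      drugs = list(drug("N02AA01", "morphine")),
      target_clcg = if (near) 16 else runif(1, 7, 13)),
    metformin_renal_failure = list(
      drugs = list(drug("A10BA02", "metformine")),
      target_clcg = if (near) 31 else runif(1, 18, 28)),
    vka_inr = list(
      drugs = list(drug("B01AA07", "acenocoumarol")),
      labs = list(lab("inr", if (near) 3.9 else round(runif(1, 4.2, 6.5), 1)))),
    vancomycin_level = list(
      drugs = list(drug("J01XA01", "vancomycine", route = "iv_intermittent",
                        conc = 0.01)),
      labs = list(lab("vancomycin_level",
                      if (near) 24 else round(runif(1, 26, 35), 1)))),
    digoxin_level = list(
      drugs = list(drug("C01AA05", "digoxine")),
      labs = list(lab("digoxin_level",
                      if (near) 2.9 else round(runif(1, 3.2, 4.5), 1)))),
    aminoglycoside_level = list(
      drugs = list(drug("J01GB03", "gentamicine", route = "iv_intermittent",
                        conc = 0.02)),
      labs = list(lab("gentamicin_level",
                      if (near) 0.9 else round(runif(1, 1.2, 2.5), 1)))),
    hypoglycemia = list(
      drugs = list(drug("A10AB05", "insuline asparte", route = "sc")),
      labs = list(lab("glucose", if (near) 4.1 else round(runif(1, 2.8, 3.8), 1)))),
    heparin_thrombopenia = list(
      drugs = list(drug("B01AB05", "enoxaparine", route = "sc")),
      labs = list(lab("platelets", if (near) 51 else round(runif(1, 20, 45))))),
    digoxin_dyskalemia = list(
      drugs = list(drug("C01AA05", "digoxine")),
      labs = list(lab("potassium", if (near) 3.6 else {
        if (runif(1) < 0.5) round(runif(1, 2.8, 3.4), 1)
        else round(runif(1, 5.6, 6.3), 1)
      }))),
    metformin_lactate = list(
      drugs = list(drug("A10BA02", "metformine")),
      labs = list(lab("lactate", if (near) 4.9 else round(runif(1, 5.5, 8), 1)))),
    anticholinergic_context = list(
      drugs = list(drug("N05AH04", "quetiapine")),
      note_keyword = if (near) NULL else "démence"),
    seizure_threshold_epilepsy = list(
      drugs = list(drug("N02AX02", "tramadol")),
      note_keyword = if (near) NULL else "épilepsie"),
    nsaid_context = list(
      drugs = list(drug("M01AE01", "ibuprofène")),
      note_keyword = if (near) NULL else "insuffisance cardiaque"),
    anticoagulant_duplication = if (near) list(
      # VKA bridged with LMWH: an excluded, intended combination
      drugs = list(drug("B01AA07", "acenocoumarol"),
                   drug("B01AB05", "enoxaparine", route = "sc"))
    ) else list(
      drugs = list(drug("B01AF02", "apixaban"),
                   drug("B01AF01", "rivaroxaban"))),
    serotonergic_duplication = if (near) list(
      drugs = list(drug("N06AB06", "sertraline"))
    ) else list(
      drugs = list(drug("N06AB06", "sertraline"),
                   drug("N02AX02", "tramadol"))),
    mtx_interval = list(
      drugs = list(drug("L04AX03", "méthotrexate")),
      admin_gap_days = if (near) 8 else 6),
    kcl_rate = list(
      drugs = list(drug("B05XA01", "chlorure de potassium",
                        route = "iv_continuous",
                        rate = if (near) 10 else round(runif(1, 10.5, 15), 1),
                        conc = 0.5))),
    kcl_concentration = list(
      drugs = list(drug("B05XA01", "chlorure de potassium",
                        route = "iv_intermittent",
                        conc = if (near) 0.08 else round(runif(1, 0.09, 0.15), 2)))),
    pc_stop(sprintf("no injection plan for rule '%s'", rule_id))
  )
}

#' Generate a synthetic inpatient cohort with known ground truth
#'
#' Builds an [ehr_store()] of `n_patients` admitted adults with background
#' medication and laboratory series, injects the configured high-risk
#' situations so they satisfy their rule's trigger exactly, and places
#' near-miss controls one minimal step outside the trigger (clearance one
#' mL/min above threshold, platelets one G/L above, a dose gap one day too
#' long, a clean admission note...). Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A list: `store` (validated [ehr_store()]), `truth` (data.frame
#'   `patient_id`, `rule_id`, `expected_alert`, `near_miss`), `as_of`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  as_of <- pc_parse_ts(config$as_of)
  n <- config$n_patients
  formulary <- pc_background_formulary()
  templates <- pc_clean_note_templates()

  roles <- rep("clean", n)
  inj_rules <- rep(names(config$injections), times = config$injections)
  n_inj <- length(inj_rules)
  n_near <- min(floor(config$near_miss_fraction * n), n - n_inj)
  near_rules <- rep(rulebook_ids(build_default_rulebook()),
                    length.out = max(n_near, 0))
  shuffled <- sample.int(n)
  inj_idx <- shuffled[seq_len(n_inj)]
  near_idx <- if (n_near > 0) shuffled[n_inj + seq_len(n_near)] else integer(0)

  patients <- list(); rx <- list(); labs <- list(); notes <- list()
  admins <- list(); truth <- list()
  rx_n <- 0L
  next_rx_id <- function() {
    rx_n <<- rx_n + 1L
    sprintf("RX%05d", rx_n)
  }

  for (i in seq_len(n)) {
    pid <- sprintf("P%04d", i)
    sex <- sample(PC_SEX, 1)
    age <- pc_sample_age(1)
    height <- if (runif(1) < 0.9) {
      round(rnorm(1, if (sex == "male") 175 else 162, 7))
    } else NA_real_
    weight <- round(rnorm(1, if (sex == "male") 78 else 66, 12), 1)
    weight <- min(max(weight, 42), 140)
    los <- rlnorm(1, log(10.5), 0.8)
    elapsed <- runif(1, 0.2, 0.9) * los
    admitted <- as_of - pc_days(min(elapsed, 25))
    discharged <- admitted + pc_days(los)
    patients[[i]] <- data.frame(
      patient_id = pid, sex = sex, age = age, height_cm = height,
      weight_kg = weight, ward_id = sprintf("W%02d", sample.int(6, 1)),
      admitted_at = pc_format_ts(admitted),
      discharged_at = pc_format_ts(discharged), stringsAsFactors = FALSE)

    role <- if (i %in% inj_idx) "inject"
            else if (i %in% near_idx) "near" else "clean"
    rule_id <- switch(role,
      inject = inj_rules[[match(i, inj_idx)]],
      near = near_rules[[match(i, near_idx)]],
      NA_character_)
    plan <- if (role == "clean") list() else {
      pc_injection_plan(rule_id, near = role == "near")
    }

    # renal profile: work backwards from a target clearance
    target_clcg <- plan$target_clcg %||% runif(1, 55, 95)
    ibw <- ideal_body_weight(height, sex)
    wsel <- dosing_weight(weight, ibw)
    creat_latest <- round(pc_creatinine_for_clcg(target_clcg, age, wsel, sex), 1)
    creat_times <- as_of - pc_days(c(18, 10, 4, 1) + runif(4, 0, 0.5))
    creat_vals <- c(round(creat_latest * runif(3, 0.7, 0.95), 1), creat_latest)
    for (j in seq_along(creat_vals)) {
      labs[[length(labs) + 1L]] <- data.frame(
        patient_id = pid, analyte = "creatinine", value = creat_vals[[j]],
        unit = "umol/L", published_at = pc_format_ts(creat_times[[j]]),
        stringsAsFactors = FALSE)
    }
    for (j in 3:4) {
      labs[[length(labs) + 1L]] <- data.frame(
        patient_id = pid, analyte = "egfr_ckdepi",
        value = round(ckd_epi(creat_vals[[j]], age, sex), 1),
        unit = "mL/min/1.73m2", published_at = pc_format_ts(creat_times[[j]]),
        stringsAsFactors = FALSE)
    }
    for (an in c("glucose", "potassium")) {
      base <- if (an == "glucose") runif(2, 4.5, 7.8) else runif(2, 3.8, 5.2)
      at <- as_of - pc_days(c(6, 2) + runif(2, 0, 0.5))
      for (j in 1:2) {
        labs[[length(labs) + 1L]] <- data.frame(
          patient_id = pid, analyte = an, value = round(base[[j]], 1),
          unit = "mmol/L", published_at = pc_format_ts(at[[j]]),
          stringsAsFactors = FALSE)
      }
    }

    # background medication
    n_bg <- min(max(rnbinom(1, size = 14, mu = 13.5), 1), nrow(formulary))
    bg <- formulary[sample.int(nrow(formulary), n_bg), , drop = FALSE]
    for (j in seq_len(nrow(bg))) {
      rx[[length(rx) + 1L]] <- data.frame(
        prescription_id = next_rx_id(), patient_id = pid,
        atc_code = bg$atc_code[[j]], drug_label = bg$drug_label[[j]],
        status = "CHECKED", route = "oral", is_prn = runif(1) < 0.1,
        dose_value = 1, dose_unit = "unit", rate_mmol_per_h = NA_real_,
        concentration_mmol_per_ml = NA_real_,
        start_at = pc_format_ts(admitted), end_at = NA_character_,
        free_text_comment = NA_character_, stringsAsFactors = FALSE)
    }
    # unsigned noise order on a rule drug: must never trigger
    if (runif(1) < 0.15) {
      rx[[length(rx) + 1L]] <- data.frame(
        prescription_id = next_rx_id(), patient_id = pid,
        atc_code = "B01AF02", drug_label = "apixaban", status = "DRAFT",
        route = "oral", is_prn = FALSE, dose_value = 5, dose_unit = "mg",
        rate_mmol_per_h = NA_real_, concentration_mmol_per_ml = NA_real_,
        start_at = pc_format_ts(admitted), end_at = NA_character_,
        free_text_comment = NA_character_, stringsAsFactors = FALSE)
    }

    # injected situation
    for (d in plan$drugs %||% list()) {
      iv <- d$route %in% c("iv_intermittent", "iv_continuous")
      rx[[length(rx) + 1L]] <- data.frame(
        prescription_id = next_rx_id(), patient_id = pid,
        atc_code = d$atc, drug_label = d$label, status = "CHECKED",
        route = d$route, is_prn = isTRUE(d$prn), dose_value = 1,
        dose_unit = "unit",
        rate_mmol_per_h = if (iv) d$rate else NA_real_,
        concentration_mmol_per_ml = if (iv) d$conc else NA_real_,
        start_at = pc_format_ts(admitted + pc_days(0.1)),
        end_at = NA_character_, free_text_comment = NA_character_,
        stringsAsFactors = FALSE)
    }
    for (l in plan$labs %||% list()) {
      unit <- analyte_vocabulary()
      labs[[length(labs) + 1L]] <- data.frame(
        patient_id = pid, analyte = l$analyte, value = l$value,
        unit = unit$unit[unit$analyte == l$analyte],
        published_at = pc_format_ts(as_of - pc_days(runif(1, 0.1, 0.8))),
        stringsAsFactors = FALSE)
    }
    if (!is.null(plan$admin_gap_days)) {
      first_dose <- as_of - pc_days(plan$admin_gap_days + 2)
      for (at in list(first_dose, first_dose + pc_days(plan$admin_gap_days))) {
        admins[[length(admins) + 1L]] <- data.frame(
          patient_id = pid, atc_code = "L04AX03",
          scheduled_at = pc_format_ts(at), given = at <= as_of,
          stringsAsFactors = FALSE)
      }
    }

    note_text <- sample(templates, 1)
    if (!is.null(plan$note_keyword)) {
      note_text <- paste0(note_text, " Problème actif : ", plan$note_keyword, ".")
    }
    notes[[length(notes) + 1L]] <- data.frame(
      patient_id = pid, note_kind = "admission_note", text = note_text,
      written_at = pc_format_ts(admitted), stringsAsFactors = FALSE)

    if (role != "clean") {
      truth[[length(truth) + 1L]] <- data.frame(
        patient_id = pid, rule_id = rule_id,
        expected_alert = role == "inject", near_miss = role == "near",
        stringsAsFactors = FALSE)
    }
  }

  store <- ehr_store(
    patients = do.call(rbind, patients),
    prescriptions = do.call(rbind, rx),
    labs = do.call(rbind, labs),
    notes = do.call(rbind, notes),
    administrations = if (length(admins)) do.call(rbind, admins))
  truth_df <- if (length(truth)) do.call(rbind, truth) else {
    data.frame(patient_id = character(0), rule_id = character(0),
               expected_alert = logical(0), near_miss = logical(0),
               stringsAsFactors = FALSE)
  }
  list(store = store, truth = truth_df, as_of = as_of)
}
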