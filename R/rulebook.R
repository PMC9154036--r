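# Declarative representation of the clinical rules and the default rulebook
# of twenty high-risk medication situations, plus its config-file round trip.

PC_RISK_CATEGORIES <- c("abnormal_lab", "contraindicated_in_context",
                        "drug_drug_interaction", "inadequate_administration")
PC_RISK_SUBCATEGORIES <- c("renal_failure", "supratherapeutic_level",
                           "abnormal_lab_value", "none")
PC_RULEBOOK_VERSION <- "1.0"

#' Construct a clinical screening rule
#'
#' A rule pairs a declarative trigger specification with classification
#' metadata and a list of context values to surface with each alert. Four
#' trigger types exist: `drug_lab` (drug set x laboratory predicate, with an
#' optional renal mode where the predicate applies to computed
#' Cockcroft-Gault clearance instead of a stored result), `drug_problem`
#' (drug set x French problem keywords in admission notes), `drug_combo`
#' (therapeutic duplication across named drug classes) and `admin_mode`
#' (flow-rate, concentration or dose-interval checks).
#'
#' @param rule_id Stable slug, unique within a rulebook.
#' @param description Human-readable statement of the high-risk situation.
#' @param risk_category One of `r paste(PC_RISK_CATEGORIES, collapse = ", ")`.
#' @param risk_subcategory Sub-category; only `abnormal_lab` rules take a
#'   value other than `"none"`.
#' @param trigger Trigger specification list (see Details in the vignette).
#' @param context_spec Character vector of context-value descriptors.
#' @param enabled Disabled rules evaluate to an empty candidate list.
#' @return An object of class `clinical_rule`.
#' @export
clinical_rule <- function(rule_id, description, risk_category,
                          risk_subcategory = "none", trigger,
                          context_spec = character(0), enabled = TRUE) {
  risk_category <- match.arg(risk_category, PC_RISK_CATEGORIES)
  risk_subcategory <- match.arg(risk_subcategory, PC_RISK_SUBCATEGORIES)
  if (risk_subcategory != "none" && risk_category != "abnormal_lab") {
    pc_stop("risk sub-categories apply only to abnormal_lab rules")
  }
  if (risk_category == "abnormal_lab" && risk_subcategory == "none") {
    pc_stop("abnormal_lab rules must carry a sub-category")
  }
  stopifnot(is.list(trigger), !is.null(trigger$type))
  if (trigger$type == "drug_lab") {
    for (b in trigger$branches) {
      if (!is.na(b$threshold) && b$threshold <= 0 && b$comparator != "outside") {
        pc_stop("thresholds must be positive")
      }
    }
  }
  structure(list(
    rule_id = rule_id,
    description = description,
    risk_category = risk_category,
    risk_subcategory = risk_subcategory,
    trigger = trigger,
    context_spec = context_spec,
    enabled = isTRUE(enabled)
  ), class = "clinical_rule")
}

pc_branch <- function(analyte, comparator, threshold, threshold_high = NA_real_,
                      drug_set = NULL) {
  list(analyte = analyte, comparator = comparator, threshold = threshold,
       threshold_high = threshold_high, drug_set = drug_set)
}

pc_trigger_drug_lab <- function(drug_set, branches,
                                renal_mode = "none", exclude_prn = FALSE,
                                window_days = 30) {
  list(type = "drug_lab", drug_set = drug_set, branches = branches,
       renal_mode = renal_mode, exclude_prn = exclude_prn,
       window_days = window_days)
}

pc_trigger_drug_problem <- function(drug_set, keyword_set,
                                    note_kind = "admission_note") {
  stopifnot(length(keyword_set) > 0)
  list(type = "drug_problem", drug_set = drug_set, keyword_set = keyword_set,
       note_kind = note_kind)
}

pc_trigger_drug_combo <- function(class_sets, excluded_pairs = list(),
                                  min_distinct = 2) {
  stopifnot(min_distinct >= 2)
  list(type = "drug_combo", class_sets = class_sets,
       excluded_pairs = excluded_pairs, min_distinct = min_distinct)
}

pc_trigger_admin_mode <- function(mode, drug_set, rate_threshold = NA_real_,
                                  conc_intermittent = NA_real_,
                                  conc_continuous = NA_real_,
                                  max_gap_days = NA_real_) {
  mode <- match.arg(mode, c("rate", "concentration", "dose_interval"))
  list(type = "admin_mode", mode = mode, drug_set = drug_set,
       rate_threshold = rate_threshold, conc_intermittent = conc_intermittent,
       conc_continuous = conc_continuous, max_gap_days = max_gap_days)
}

#' Build the default rulebook of twenty clinical rules
#'
#' Twelve abnormal-laboratory-value rules (four renal-failure, four
#' supratherapeutic drug level, four other abnormal values), three
#' contraindication-in-context rules driven by French problem keywords in
#' admission notes, two therapeutic-duplication rules and three
#' administration-mode rules. Thresholds and comparator inclusivities follow
#' the deployed rule definitions: `<=`/`>=` are inclusive, `>` strict.
#'
#' @return An object of class `rulebook` holding 20 enabled rules, a version
#'   tag, and the (initially empty, user-fillable) list of strong P-gp/CYP3A4
#'   inducers and inhibitors displayed as context with the anticoagulant
#'   renal rules.
#' @seealso [evaluate_all()], [write_rulebook()]
#' @export
build_default_rulebook <- function() {
  rules <- list(
    # --- abnormal_lab / renal_failure -----------------------------------
    clinical_rule(
      "doac_renal_failure",
      "Direct oral anticoagulant in acute renal failure (ClCG <= 30 mL/min)",
      "abnormal_lab", "renal_failure",
      pc_trigger_drug_lab(
        pc_drug_set(atc = c("B01AF02", "B01AE07", "B01AF03", "B01AF01"),
                    labels = c("apixaban", "dabigatran", "edoxaban",
                               "rivaroxaban")),
        list(pc_branch("clcg", "<=", 30)),
        renal_mode = "clcg_selected_weight"),
      context_spec = c("renal_assessment", "previous_creatinine",
                       "pgp_cyp3a4_modulators")),
    clinical_rule(
      "colchicine_renal_failure",
      "Colchicine in acute renal failure (ClCG <= 30 mL/min)",
      "abnormal_lab", "renal_failure",
      pc_trigger_drug_lab(
        pc_drug_set(atc = "M04AC01", labels = "colchicine"),
        list(pc_branch("clcg", "<=", 30)),
        renal_mode = "clcg_selected_weight"),
      context_spec = c("renal_assessment", "previous_creatinine",
                       "pgp_cyp3a4_modulators")),
    clinical_rule(
      "morphine_renal_failure",
      "Morphine in acute renal failure (ClCG <= 15 mL/min)",
      "abnormal_lab", "renal_failure",
      pc_trigger_drug_lab(
        pc_drug_set(atc = "N02AA01", labels = "morphine"),
        list(pc_branch("clcg", "<=", 15)),
        renal_mode = "clcg_selected_weight"),
      context_spec = c("renal_assessment", "previous_creatinine")),
    clinical_rule(
      "metformin_renal_failure",
      "Metformin in acute renal failure (ClCG <= 30 mL/min)",
      "abnormal_lab", "renal_failure",
      pc_trigger_drug_lab(
        pc_drug_set(atc = "A10BA02", labels = "metformin"),
        list(pc_branch("clcg", "<=", 30)),
        renal_mode = "clcg_selected_weight"),
      context_spec = c("renal_assessment", "previous_creatinine")),
    # --- abnormal_lab / supratherapeutic_level --------------------------
    clinical_rule(
      "vka_inr",
      "Vitamin K antagonist with supratherapeutic INR (>= 4)",
      "abnormal_lab", "supratherapeutic_level",
      pc_trigger_drug_lab(
        pc_drug_set(atc = "B01AA",
                    labels = c("acenocoumarol", "fluindione", "warfarin",
                               "phenprocoumon")),
        list(pc_branch("inr", ">=", 4))),
      context_spec = c("previous_labs", "medication_history")),
    clinical_rule(
      "vancomycin_level",
      "Vancomycin with supratherapeutic trough (>= 25 mg/L)",
      "abnormal_lab", "supratherapeutic_level",
      pc_trigger_drug_lab(
        pc_drug_set(atc = "J01XA01", labels = "vancomycin"),
        list(pc_branch("vancomycin_level", ">=", 25))),
      context_spec = "previous_labs"),
    clinical_rule(
      "digoxin_level",
      "Digoxin with supratherapeutic digoxinemia (>= 3 nmol/L)",
      "abnormal_lab", "supratherapeutic_level",
      pc_trigger_drug_lab(
        pc_drug_set(atc = "C01AA05", labels = c("digoxin", "digoxine")),
        list(pc_branch("digoxin_level", ">=", 3))),
      context_spec = c("previous_labs", "medication_history")),
    clinical_rule(
      "aminoglycoside_level",
      "Aminoglycoside with supratherapeutic trough (gentamicin/tobramycin >= 1, amikacin >= 5 mg/L)",
      "abnormal_lab", "supratherapeutic_level",
      pc_trigger_drug_lab(
        pc_drug_set(atc = c("J01GB03", "J01GB01", "J01GB06"),
                    labels = c("gentamicin", "tobramycin", "amikacin")),
        list(
          pc_branch("gentamicin_level", ">=", 1,
                    drug_set = pc_drug_set(atc = "J01GB03", labels = "gentamicin")),
          pc_branch("tobramycin_level", ">=", 1,
                    drug_set = pc_drug_set(atc = "J01GB01", labels = "tobramycin")),
          pc_branch("amikacin_level", ">=", 5,
                    drug_set = pc_drug_set(atc = "J01GB06", labels = "amikacin")))),
      context_spec = "previous_labs"),
    # --- abnormal_lab / abnormal_lab_value ------------------------------
    clinical_rule(
      "hypoglycemia",
      "Blood-glucose-lowering drug (insulins and oral agents, PRN excluded) with hypoglycemia (glucose <= 4 mmol/L)",
      "abnormal_lab", "abnormal_lab_value",
      pc_trigger_drug_lab(
        pc_drug_set(atc = c("A10A", "A10B")),
        list(pc_branch("glucose", "<=", 4)),
        exclude_prn = TRUE),
      context_spec = "previous_labs"),
    clinical_rule(
      "heparin_thrombopenia",
      "Heparin (LMWH or UFH) with thrombopenia (platelets <= 50 G/L)",
      "abnormal_lab", "abnormal_lab_value",
      pc_trigger_drug_lab(
        pc_drug_set(atc = "B01AB",
                    labels = c("heparin", "enoxaparin", "dalteparin",
                               "nadroparin", "tinzaparin")),
        list(pc_branch("platelets", "<=", 50))),
      context_spec = c("previous_labs", "medication_history")),
    clinical_rule(
      "digoxin_dyskalemia",
      "Digoxin with dyskalemia (potassium <= 3.5 or >= 5.5 mmol/L)",
      "abnormal_lab", "abnormal_lab_value",
      pc_trigger_drug_lab(
        pc_drug_set(atc = "C01AA05", labels = c("digoxin", "digoxine")),
        list(pc_branch("potassium", "outside", 3.5, threshold_high = 5.5))),
      context_spec = c("previous_labs", "medication_history")),
    clinical_rule(
      "metformin_lactate",
      "Metformin with hyperlactatemia (lactate >= 5.0 mmol/L)",
      "abnormal_lab", "abnormal_lab_value",
      pc_trigger_drug_lab(
        pc_drug_set(atc = "A10BA02", labels = "metformin"),
        list(pc_branch("lactate", ">=", 5))),
      context_spec = "previous_labs"),
    # --- contraindicated_in_context -------------------------------------
    clinical_rule(
      "anticholinergic_context",
      "Anticholinergic drug with a predisposing comorbidity in the admission note",
      "contraindicated_in_context", trigger =
        pc_trigger_drug_problem(
          pc_anticholinergic_set(),
          keyword_set = c("démence", "état confusionnel", "confusion",
                          "globe urinaire", "prostatisme",
                          "rétention urinaire", "glaucome",
                          "trouble de la conduction")),
      context_spec = "medication_history"),
    clinical_rule(
      "seizure_threshold_epilepsy",
      "Drug potentially lowering the seizure threshold with epilepsy in the admission note",
      "contraindicated_in_context", trigger =
        pc_trigger_drug_problem(pc_seizure_set(),
                                keyword_set = "épilepsie"),
      context_spec = "medication_history"),
    clinical_rule(
      "nsaid_context",
      "NSAID or metamizole with a predisposing comorbidity in the admission note",
      "contraindicated_in_context", trigger =
        pc_trigger_drug_problem(
          pc_drug_set(atc = c("M01A", "N02BB02"), labels = "metamizole"),
          keyword_set = c("insuffisance rénale chronique",
                          "insuffisance cardiaque",
                          "infarctus du myocarde", "ulcère gastrique",
                          "ulcère duodénal",
                          "ulcère gastroduodénal")),
      context_spec = "medication_history"),
    # --- drug_drug_interaction ------------------------------------------
    clinical_rule(
      "anticoagulant_duplication",
      "Co-prescription of two anticoagulants (VKA with LMWH or UFH excluded)",
      "drug_drug_interaction", trigger =
        pc_trigger_drug_combo(
          pc_anticoagulant_classes(),
          excluded_pairs = list(c("vka", "lmwh"), c("vka", "ufh")))),
    clinical_rule(
      "serotonergic_duplication",
      "Co-prescription of two serotonergic drugs",
      "drug_drug_interaction", trigger =
        pc_trigger_drug_combo(pc_serotonergic_classes()),
      context_spec = "medication_history"),
    # --- inadequate_administration --------------------------------------
    clinical_rule(
      "mtx_interval",
      "Two methotrexate doses scheduled within 7 days",
      "inadequate_administration", trigger =
        pc_trigger_admin_mode(
          "dose_interval",
          pc_drug_set(atc = c("L01BA01", "L04AX03"), labels = "methotrexate"),
          max_gap_days = 7)),
    clinical_rule(
      "kcl_rate",
      "Intravenous potassium chloride at a flow rate > 10 mmol/h",
      "inadequate_administration", trigger =
        pc_trigger_admin_mode(
          "rate",
          pc_drug_set(atc = "B05XA01", labels = "potassium chloride"),
          rate_threshold = 10)),
    clinical_rule(
      "kcl_concentration",
      "Intravenous potassium chloride too concentrated (> 0.08 mmol/mL intermittent, > 1.00 mmol/mL continuous)",
      "inadequate_administration", trigger =
        pc_trigger_admin_mode(
          "concentration",
          pc_drug_set(atc = "B05XA01", labels = "potassium chloride"),
          conc_intermittent = 0.08, conc_continuous = 1.00))
  )
  ids <- vapply(rules, `[[`, character(1), "rule_id")
  stopifnot(!anyDuplicated(ids), length(rules) == 20L)
  structure(list(
    version = PC_RULEBOOK_VERSION,
    rules = rules,
    pgp_cyp3a4_modulators = pc_drug_set()
  ), class = "rulebook")
}

#' @export
print.rulebook <- function(x, ...) {
  cat(sprintf("<rulebook v%s> %d rules (%d enabled)\n", x$version,
              length(x$rules),
              sum(vapply(x$rules, `[[`, logical(1), "enabled"))))
  for (r in x$rules) {
    cat(sprintf("  [%s] %-28s %s\n",
                substr(r$risk_category, 1, 1), r$rule_id, r$description))
  }
  invisible(x)
}

rulebook_ids <- function(rulebook) {
  vapply(rulebook$rules, `[[`, character(1), "rule_id")
}

rulebook_rule <- function(rulebook, rule_id) {
  idx <- match(rule_id, rulebook_ids(rulebook))
  if (is.na(idx)) pc_stop(sprintf("unknown rule '%s'", rule_id))
  rulebook$rules[[idx]]
}

# ---- config-file round trip -------------------------------------------

pc_set_to_list <- function(set) {
  list(atc = as.list(set$atc), labels = as.list(set$labels))
}

pc_set_from_list <- function(l) {
  pc_drug_set(atc = as.character(unlist(l$atc)),
              labels = as.character(unlist(l$labels)))
}

#' Write a rulebook to a human-editable YAML config file
#'
#' The shipped default (`inst/extdata/rulebook-default.yaml`) reproduces
#' [build_default_rulebook()]; edits to thresholds, drug lists or keyword
#' lists survive a [read_rulebook()] round trip without semantic change.
#'
#' @param rulebook A `rulebook`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rulebook <- function(rulebook, path) {
  stopifnot(inherits(rulebook, "rulebook"))
  as_plain <- function(r) {
    t <- r$trigger
    tl <- switch(t$type,
      drug_lab = list(
        type = "drug_lab", drug_set = pc_set_to_list(t$drug_set),
        branches = lapply(t$branches, function(b) {
          out <- list(analyte = b$analyte, comparator = b$comparator,
                      threshold = b$threshold)
          if (!is.na(b$threshold_high)) out$threshold_high <- b$threshold_high
          if (!is.null(b$drug_set)) out$drug_set <- pc_set_to_list(b$drug_set)
          out
        }),
        renal_mode = t$renal_mode, exclude_prn = t$exclude_prn,
        window_days = t$window_days),
      drug_problem = list(
        type = "drug_problem", drug_set = pc_set_to_list(t$drug_set),
        keyword_set = as.list(t$keyword_set), note_kind = t$note_kind),
      drug_combo = list(
        type = "drug_combo",
        class_sets = lapply(t$class_sets, pc_set_to_list),
        excluded_pairs = lapply(t$excluded_pairs, as.list),
        min_distinct = t$min_distinct),
      admin_mode = {
        out <- list(type = "admin_mode", mode = t$mode,
                    drug_set = pc_set_to_list(t$drug_set))
        for (f in c("rate_threshold", "conc_intermittent", "conc_continuous",
                    "max_gap_days")) {
          if (!is.na(t[[f]])) out[[f]] <- t[[f]]
        }
        out
      })
    list(rule_id = r$rule_id, description = r$description,
         risk_category = r$risk_category,
         risk_subcategory = r$risk_subcategory,
         enabled = r$enabled, trigger = tl,
         context_spec = as.list(r$context_spec))
  }
  doc <- list(version = rulebook$version,
              pgp_cyp3a4_modulators = pc_set_to_list(rulebook$pgp_cyp3a4_modulators),
              rules = lapply(rulebook$rules, as_plain))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a rulebook from a YAML config file
#'
#' @param path Config file written by [write_rulebook()] (or hand-edited).
#' @return A `rulebook`.
#' @export
read_rulebook <- function(path) {
  if (!file.exists(path)) pc_stop(sprintf("rulebook file not found: %s", path))
  doc <- yaml::read_yaml(path)
  parse_rule <- function(r) {
    t <- r$trigger
    trig <- switch(t$type,
      drug_lab = pc_trigger_drug_lab(
        pc_set_from_list(t$drug_set),
        branches = lapply(t$branches, function(b) {
          pc_branch(b$analyte, b$comparator, as.numeric(b$threshold),
                    threshold_high = as.numeric(b$threshold_high %||% NA),
                    drug_set = if (!is.null(b$drug_set)) pc_set_from_list(b$drug_set))
        }),
        renal_mode = t$renal_mode %||% "none",
        exclude_prn = isTRUE(t$exclude_prn),
        window_days = as.numeric(t$window_days %||% 30)),
      drug_problem = pc_trigger_drug_problem(
        pc_set_from_list(t$drug_set),
        keyword_set = as.character(unlist(t$keyword_set)),
        note_kind = t$note_kind %||% "admission_note"),
      drug_combo = pc_trigger_drug_combo(
        lapply(t$class_sets, pc_set_from_list),
        excluded_pairs = lapply(t$excluded_pairs, function(p) as.character(unlist(p))),
        min_distinct = as.numeric(t$min_distinct %||% 2)),
      admin_mode = pc_trigger_admin_mode(
        t$mode, pc_set_from_list(t$drug_set),
        rate_threshold = as.numeric(t$rate_threshold %||% NA),
        conc_intermittent = as.numeric(t$conc_intermittent %||% NA),
        conc_continuous = as.numeric(t$conc_continuous %||% NA),
        max_gap_days = as.numeric(t$max_gap_days %||% NA)),
      pc_stop(sprintf("unknown trigger type '%s'", t$type)))
    clinical_rule(r$rule_id, r$description, r$risk_category,
                  r$risk_subcategory %||% "none", trig,
                  context_spec = as.character(unlist(r$context_spec)),
                  enabled = isTRUE(r$enabled))
  }
  structure(list(
    version = doc$version %||% PC_RULEBOOK_VERSION,
    rules = lapply(doc$rules, parse_rule),
    pgp_cyp3a4_modulators = pc_set_from_list(doc$pgp_cyp3a4_modulators)
  ), class = "rulebook")
}
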