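# Independent brute-force screening oracle. Re-derives every rule by naive
# nested scans over the raw document data frames with inline clinical
# constants -- no staged query primitives, no rulebook objects -- so that
# agreement with evaluate_all() is a genuine dual-route check.

bf_fold <- function(x) {
  chartr("àâäéèêëîïôöùûüç",
         "aaaeeeeiioouuuc", tolower(x))
}
bf_norm <- function(x) sub("e$", "", gsub("[[:space:]]+", " ", bf_fold(trimws(x))))

bf_has_prefix <- function(atc, prefixes) {
  any(vapply(prefixes, function(p) startsWith(toupper(atc), p), logical(1)))
}

brute_force_screen <- function(store, as_of) {
  as_of <- as.POSIXct(as_of, tz = "UTC")
  win_lo <- as_of - as.difftime(30, units = "days")
  P <- store$patients; RX <- store$prescriptions; LB <- store$labs
  NT <- store$notes; AD <- store$administrations

  latest_lab <- function(pid, analyte) {
    v <- NA_real_; best <- -Inf; best_i <- -1
    for (i in seq_len(nrow(LB))) {
      if (LB$patient_id[i] != pid || LB$analyte[i] != analyte) next
      t <- as.numeric(LB$published_at[i])
      if (t <= as.numeric(win_lo) || t > as.numeric(as_of)) next
      if (t > best || (t == best && i > best_i)) {
        best <- t; best_i <- i; v <- LB$value[i]
      }
    }
    v
  }

  res <- character(0)
  hit <- function(pid, rule) res <<- c(res, paste(pid, rule))

  serotonergic <- bf_norm(c(
    "amitriptyline", "bromocriptine", "bupropion", "buspirone", "cabergoline",
    "carbamazepine", "citalopram", "clomipramine", "clozapine",
    "dextromethorphan", "dihydroergotamine", "dosulepin", "doxepin",
    "eletriptan", "ergotamine", "escitalopram", "fentanyl", "fluoxetine",
    "fluvoxamine", "haloperidol", "imipramine", "isoniazid", "lamotrigine",
    "linezolid", "lithium", "maprotiline", "methadone", "metoclopramide",
    "mianserin", "mirtazapine", "moclobemide", "naratriptan", "nortriptyline",
    "olanzapine", "ondansetron", "oxycodone", "paroxetine", "pergolide",
    "pethidine", "quetiapine", "risperidone", "rizatriptan", "selegiline",
    "sertraline", "sibutramine", "sumatriptan", "tramadol", "trazodone",
    "trimipramine", "valproate", "venlafaxine", "zolmitriptan"))
  anticholinergic_labels <- bf_norm(c(
    "acepromazine", "antazoline", "azatadine", "bamipine", "buclizine",
    "carbamazepine", "chlorcyclizine", "chlorpromazine", "cinnarizine",
    "clozapine", "cyamemazine", "cyclizine", "cyproheptadine", "deptropine",
    "dimetindene", "disopyramide", "fluphenazine", "hydroxyzine",
    "hyoscyamine", "levomepromazine", "loxapine", "mebhydrolin", "meclozine",
    "nefopam", "oxatomide", "oxcarbazepine", "paroxetine", "pethidine",
    "phenindamine", "pimethixene", "pimozide", "piritramide", "pizotifen",
    "propantheline", "pyrrobutamine", "quetiapine", "scopolamine",
    "thenalidine", "thioridazine", "thiothixene", "tizanidine"))
  anticholinergic_prefixes <- c("R06AA", "R06AB", "R06AC", "R06AD", "N04A",
                                "A03", "G04BD", "N06AA")
  seizure_labels <- bf_norm(c(
    "azithromycin", "bupropion", "busulfan", "carmustine", "chlorambucil",
    "chlorpromazine", "clonidine", "clozapine", "cyamemazine", "disopyramide",
    "domperidone", "enflurane", "ephedrine", "flumazenil", "foscarnet",
    "ganciclovir", "haloperidol", "hydroxyzine", "ketamine", "ketoconazole",
    "levomepromazine", "lidocaine", "lithium", "loxapine", "mefloquine",
    "methotrexate", "methylphenidate", "metronidazole", "midecamycin",
    "nefopam", "oxetorone", "oxybutynin", "pentazocine", "pethidine",
    "phenylpropanolamine", "pimozide", "piritramide", "pizotifen",
    "propantheline", "pyrimethamine", "scopolamine", "terbutaline",
    "theophylline", "tramadol", "vincristine"))
  seizure_prefixes <- c("R06", "J01C", "J01D", "J01M", "A02BA", "N06AB",
                        "L04AD", "M03B", "N05AA", "N05AB", "N04A", "G04BD",
                        "N06AA")
  antichol_kw <- bf_fold(c("démence", "état confusionnel", "confusion",
                           "globe urinaire", "prostatisme",
                           "rétention urinaire", "glaucome",
                           "trouble de la conduction"))
  nsaid_kw <- bf_fold(c("insuffisance rénale chronique",
                        "insuffisance cardiaque", "infarctus du myocarde",
                        "ulcère gastrique", "ulcère duodénal",
                        "ulcère gastroduodénal"))

  for (p in seq_len(nrow(P))) {
    pid <- P$patient_id[p]
    sex <- P$sex[p]; age <- P$age[p]
    arx <- list()
    for (i in seq_len(nrow(RX))) {
      if (RX$patient_id[i] != pid) next
      if (RX$status[i] != "CHECKED") next
      if (is.na(RX$start_at[i]) || RX$start_at[i] > as_of) next
      if (!is.na(RX$end_at[i]) && RX$end_at[i] <= as_of) next
      arx[[length(arx) + 1L]] <- RX[i, ]
    }
    has_drug <- function(prefixes = character(0), labels = character(0),
                         require_non_prn = FALSE) {
      for (r in arx) {
        if (require_non_prn && isTRUE(r$is_prn)) next
        if (length(prefixes) && bf_has_prefix(r$atc_code, prefixes)) return(TRUE)
        if (length(labels) && bf_norm(r$drug_label) %in% labels) return(TRUE)
      }
      FALSE
    }

    # Cockcroft-Gault on lowest of measured and Devine ideal weight
    clcg <- NA_real_
    creat <- latest_lab(pid, "creatinine")
    if (!is.na(creat) && !is.na(age) && age >= 18) {
      ibw <- if (is.na(P$height_cm[p])) NA_real_ else {
        max(0, (if (sex == "male") 50 else 45.5) + 0.9 * (P$height_cm[p] - 152))
      }
      w <- suppressWarnings(min(c(P$weight_kg[p], ibw), na.rm = TRUE))
      if (is.finite(w)) {
        clcg <- max(0, (140 - age) * w * (if (sex == "male") 1.23 else 1.04) / creat)
      }
    }

    if (!is.na(clcg)) {
      if (clcg <= 30 && has_drug(c("B01AF02", "B01AE07", "B01AF03", "B01AF01"),
                                 bf_norm(c("apixaban", "dabigatran", "edoxaban",
                                           "rivaroxaban")))) {
        hit(pid, "doac_renal_failure")
      }
      if (clcg <= 30 && has_drug("M04AC01", bf_norm("colchicine"))) {
        hit(pid, "colchicine_renal_failure")
      }
      if (clcg <= 15 && has_drug("N02AA01", bf_norm("morphine"))) {
        hit(pid, "morphine_renal_failure")
      }
      if (clcg <= 30 && has_drug("A10BA02", bf_norm("metformin"))) {
        hit(pid, "metformin_renal_failure")
      }
    }

    inr <- latest_lab(pid, "inr")
    if (!is.na(inr) && inr >= 4 &&
        has_drug("B01AA", bf_norm(c("acenocoumarol", "fluindione", "warfarin",
                                    "phenprocoumon")))) {
      hit(pid, "vka_inr")
    }
    vanco <- latest_lab(pid, "vancomycin_level")
    if (!is.na(vanco) && vanco >= 25 && has_drug("J01XA01", bf_norm("vancomycin"))) {
      hit(pid, "vancomycin_level")
    }
    dig <- latest_lab(pid, "digoxin_level")
    if (!is.na(dig) && dig >= 3 && has_drug("C01AA05", bf_norm("digoxin"))) {
      hit(pid, "digoxin_level")
    }
    gent <- latest_lab(pid, "gentamicin_level")
    tobra <- latest_lab(pid, "tobramycin_level")
    amik <- latest_lab(pid, "amikacin_level")
    if ((!is.na(gent) && gent >= 1 && has_drug("J01GB03", bf_norm("gentamicin"))) ||
        (!is.na(tobra) && tobra >= 1 && has_drug("J01GB01", bf_norm("tobramycin"))) ||
        (!is.na(amik) && amik >= 5 && has_drug("J01GB06", bf_norm("amikacin")))) {
      hit(pid, "aminoglycoside_level")
    }

    glu <- latest_lab(pid, "glucose")
    if (!is.na(glu) && glu <= 4 &&
        has_drug(c("A10A", "A10B"), require_non_prn = TRUE)) {
      hit(pid, "hypoglycemia")
    }
    plt <- latest_lab(pid, "platelets")
    if (!is.na(plt) && plt <= 50 &&
        has_drug("B01AB", bf_norm(c("heparin", "enoxaparin", "dalteparin",
                                    "nadroparin", "tinzaparin")))) {
      hit(pid, "heparin_thrombopenia")
    }
    k <- latest_lab(pid, "potassium")
    if (!is.na(k) && (k <= 3.5 || k >= 5.5) &&
        has_drug("C01AA05", bf_norm("digoxin"))) {
      hit(pid, "digoxin_dyskalemia")
    }
    lact <- latest_lab(pid, "lactate")
    if (!is.na(lact) && lact >= 5 && has_drug("A10BA02", bf_norm("metformin"))) {
      hit(pid, "metformin_lactate")
    }

    # keyword rules over admission notes
    note_has <- function(keywords) {
      for (i in seq_len(nrow(NT))) {
        if (NT$patient_id[i] != pid || NT$note_kind[i] != "admission_note") next
        txt <- bf_fold(NT$text[i])
        for (kw in keywords) if (grepl(kw, txt, fixed = TRUE)) return(TRUE)
      }
      FALSE
    }
    if (has_drug(anticholinergic_prefixes, anticholinergic_labels) &&
        note_has(antichol_kw)) {
      hit(pid, "anticholinergic_context")
    }
    if (has_drug(seizure_prefixes, seizure_labels) &&
        note_has(bf_fold("épilepsie"))) {
      hit(pid, "seizure_threshold_epilepsy")
    }
    if (has_drug(c("M01A", "N02BB02"), bf_norm("metamizole")) &&
        note_has(nsaid_kw)) {
      hit(pid, "nsaid_context")
    }

    # anticoagulant duplication: class per active prescription, VKA+heparin
    # pairs excluded
    classes <- character(0)
    for (r in arx) {
      cl <- if (bf_has_prefix(r$atc_code, "B01AA") ||
                bf_norm(r$drug_label) %in% bf_norm(c("acenocoumarol", "fluindione",
                                                     "phenprocoumon", "warfarin"))) "vka"
        else if (bf_has_prefix(r$atc_code, c("B01AF02", "B01AE07", "B01AF01")) ||
                 bf_norm(r$drug_label) %in% bf_norm(c("apixaban", "dabigatran",
                                                      "rivaroxaban"))) "doac"
        else if (bf_has_prefix(r$atc_code, c("B01AB04", "B01AB05", "B01AB06",
                                             "B01AB10")) ||
                 bf_norm(r$drug_label) %in% bf_norm(c("dalteparin", "enoxaparin",
                                                      "nadroparin", "tinzaparin"))) "lmwh"
        else if (bf_has_prefix(r$atc_code, "B01AB01") ||
                 bf_norm(r$drug_label) == bf_norm("heparin")) "ufh"
        else NA_character_
      if (!is.na(cl)) classes <- c(classes, cl)
    }
    if (length(classes) >= 2) {
      found <- FALSE
      for (a in seq_along(classes)) for (b in seq_along(classes)) {
        if (a >= b) next
        pair <- sort(c(classes[a], classes[b]))
        if (identical(pair, c("lmwh", "vka")) || identical(pair, c("ufh", "vka"))) next
        found <- TRUE
      }
      if (found) hit(pid, "anticoagulant_duplication")
    }
    n_sero <- 0
    for (r in arx) if (bf_norm(r$drug_label) %in% serotonergic) n_sero <- n_sero + 1
    if (n_sero >= 2) hit(pid, "serotonergic_duplication")

    # administration-mode rules
    mtx_times <- numeric(0)
    for (i in seq_len(nrow(AD))) {
      if (AD$patient_id[i] != pid) next
      if (bf_has_prefix(AD$atc_code[i], c("L01BA01", "L04AX03"))) {
        mtx_times <- c(mtx_times, as.numeric(AD$scheduled_at[i]))
      }
    }
    if (length(mtx_times) >= 2) {
      found <- FALSE
      for (a in seq_along(mtx_times)) for (b in seq_along(mtx_times)) {
        if (a >= b) next
        gap <- abs(mtx_times[a] - mtx_times[b]) / 86400
        if (gap > 0 && gap <= 7) found <- TRUE
      }
      if (found) hit(pid, "mtx_interval")
    }
    kcl_rate <- FALSE; kcl_conc <- FALSE
    for (r in arx) {
      if (!(bf_has_prefix(r$atc_code, "B05XA01") ||
            bf_norm(r$drug_label) == bf_norm("potassium chloride"))) next
      if (!r$route %in% c("iv_intermittent", "iv_continuous")) next
      if (!is.na(r$rate_mmol_per_h) && r$rate_mmol_per_h > 10) kcl_rate <- TRUE
      if (!is.na(r$concentration_mmol_per_ml)) {
        lim <- if (r$route == "iv_intermittent") 0.08 else 1.00
        if (r$concentration_mmol_per_ml > lim) kcl_conc <- TRUE
      }
    }
    if (kcl_rate) hit(pid, "kcl_rate")
    if (kcl_conc) hit(pid, "kcl_concentration")
  }
  sort(res)
}
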