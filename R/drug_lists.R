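# Curated drug sets backing the default rulebook. Classes are encoded as ATC
# prefixes; individual substances as normalized labels (and exact ATC codes
# where the substance has an unambiguous one). The long anticholinergic,
# seizure-threshold and serotonergic lists are editable through the rulebook
# config file.

pc_drug_set <- function(atc = character(0), labels = character(0)) {
  list(atc = toupper(atc), labels = pc_normalize_label(labels))
}

# Substances with anticholinergic burden; class entries cover aminoalkyl-ether
# / alkylamine / ethylenediamine / phenothiazine antihistamines (R06AA-R06AD),
# antimuscarinic antiparkinsonians (N04A), functional-GI and urinary
# antispasmodics (A03, G04BD) and tricyclic-type reuptake inhibitors (N06AA).
pc_anticholinergic_set <- function() {
  pc_drug_set(
    atc = c("R06AA", "R06AB", "R06AC", "R06AD", "N04A", "A03", "G04BD", "N06AA"),
    labels = c(
      "acepromazine", "antazoline", "azatadine", "bamipine", "buclizine",
      "carbamazepine", "chlorcyclizine", "chlorpromazine", "cinnarizine",
      "clozapine", "cyamemazine", "cyclizine", "cyproheptadine", "deptropine",
      "dimetindene", "disopyramide", "fluphenazine", "hydroxyzine",
      "hyoscyamine", "levomepromazine", "loxapine", "mebhydrolin", "meclozine",
      "nefopam", "oxatomide", "oxcarbazepine", "paroxetine", "pethidine",
      "phenindamine", "pimethixene", "pimozide", "piritramide", "pizotifen",
      "propantheline", "pyrrobutamine", "quetiapine", "scopolamine",
      "thenalidine", "thioridazine", "thiothixene", "tizanidine"
    )
  )
}

# Drugs that may lower the seizure threshold; class entries cover systemic
# antihistamines (R06), penicillins and other beta-lactams (J01C, J01D),
# quinolones (J01M), H2 antagonists (A02BA), SSRIs (N06AB), calcineurin
# inhibitors (L04AD), centrally acting muscle relaxants (M03B) and
# phenothiazine antipsychotics (N05AA, N05AB).
pc_seizure_set <- function() {
  pc_drug_set(
    atc = c("R06", "J01C", "J01D", "J01M", "A02BA", "N06AB", "L04AD", "M03B",
            "N05AA", "N05AB", "N04A", "G04BD", "N06AA"),
    labels = c(
      "azithromycin", "bupropion", "busulfan", "carmustine", "chlorambucil",
      "chlorpromazine", "clonidine", "clozapine", "cyamemazine",
      "disopyramide", "domperidone", "enflurane", "ephedrine", "flumazenil",
      "foscarnet", "ganciclovir", "haloperidol", "hydroxyzine", "ketamine",
      "ketoconazole", "levomepromazine", "lidocaine", "lithium", "loxapine",
      "mefloquine", "methotrexate", "methylphenidate", "metronidazole",
      "midecamycin", "nefopam", "oxetorone", "oxybutynin", "pentazocine",
      "pethidine", "phenylpropanolamine", "pimozide", "piritramide",
      "pizotifen", "propantheline", "pyrimethamine", "scopolamine",
      "terbutaline", "theophylline", "tramadol", "vincristine"
    )
  )
}

pc_serotonergic_set <- function() {
  pc_drug_set(labels = c(
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
    "trimipramine", "valproate", "venlafaxine", "zolmitriptan"
  ))
}

# Anticoagulant classes for the therapeutic-duplication rule. Edoxaban is a
# DOAC for the renal rule but is not part of the duplication set (fidelity to
# the deployed rule definitions over symmetry).
pc_anticoagulant_classes <- function() {
  list(
    vka = pc_drug_set(
      atc = "B01AA",
      labels = c("acenocoumarol", "fluindione", "phenprocoumon", "warfarin")),
    doac = pc_drug_set(
      atc = c("B01AF02", "B01AE07", "B01AF01"),
      labels = c("apixaban", "dabigatran", "rivaroxaban")),
    lmwh = pc_drug_set(
      atc = c("B01AB04", "B01AB05", "B01AB06", "B01AB10"),
      labels = c("dalteparin", "enoxaparin", "nadroparin", "tinzaparin")),
    ufh = pc_drug_set(atc = "B01AB01", labels = "heparin")
  )
}

# Serotonergic duplication treats each substance as its own class.
pc_serotonergic_classes <- function() {
  set <- pc_serotonergic_set()
  classes <- lapply(set$labels, function(l) pc_drug_set(labels = l))
  names(classes) <- set$labels
  classes
}
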