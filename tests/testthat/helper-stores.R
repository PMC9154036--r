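# Small hand-built stores for unit and boundary tests.

AS_OF <- "2020-04-15T08:00"

default_patient <- function(patient_id = "P1", sex = "male", age = 40L,
                            height_cm = NA_real_, weight_kg = 60) {
  data.frame(patient_id = patient_id, sex = sex, age = age,
             height_cm = height_cm, weight_kg = weight_kg, ward_id = "W01",
             admitted_at = "2020-04-01T10:00", discharged_at = NA_character_,
             stringsAsFactors = FALSE)
}

rx_row <- function(prescription_id = "RX1", patient_id = "P1",
                   atc_code = "N02BE01", drug_label = "paracetamol",
                   status = "CHECKED", route = "oral", is_prn = FALSE,
                   rate_mmol_per_h = NA_real_,
                   concentration_mmol_per_ml = NA_real_,
                   start_at = "2020-04-02T08:00", end_at = NA_character_) {
  data.frame(prescription_id = prescription_id, patient_id = patient_id,
             atc_code = atc_code, drug_label = drug_label, status = status,
             route = route, is_prn = is_prn, dose_value = 1,
             dose_unit = "unit", rate_mmol_per_h = rate_mmol_per_h,
             concentration_mmol_per_ml = concentration_mmol_per_ml,
             start_at = start_at, end_at = end_at,
             free_text_comment = NA_character_, stringsAsFactors = FALSE)
}

lab_row <- function(patient_id = "P1", analyte = "creatinine", value = 80,
                    unit = NULL, published_at = "2020-04-14T09:00") {
  vocab <- analyte_vocabulary()
  if (is.null(unit)) unit <- vocab$unit[vocab$analyte == analyte]
  data.frame(patient_id = patient_id, analyte = analyte, value = value,
             unit = unit, published_at = published_at,
             stringsAsFactors = FALSE)
}

note_row <- function(patient_id = "P1", text = "Patient admis pour pneumonie.",
                     written_at = "2020-04-01T11:00") {
  data.frame(patient_id = patient_id, note_kind = "admission_note",
             text = text, written_at = written_at, stringsAsFactors = FALSE)
}

admin_row <- function(patient_id = "P1", atc_code = "L04AX03",
                      scheduled_at = "2020-04-10T09:00", given = TRUE) {
  data.frame(patient_id = patient_id, atc_code = atc_code,
             scheduled_at = scheduled_at, given = given,
             stringsAsFactors = FALSE)
}

tiny_store <- function(prescriptions = NULL, labs = NULL, notes = NULL,
                       administrations = NULL, patients = default_patient()) {
  ehr_store(patients = patients, prescriptions = prescriptions, labs = labs,
            notes = notes, administrations = administrations)
}

# (patient, rule) pairs fired, as sorted "pid rule" strings
fired_set <- function(candidates) {
  ct <- candidates_table(candidates)
  sort(paste(ct$patient_id, ct$rule_id))
}
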