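# hand-built cohort pieces for unit tests; dates are day numbers on a fixed
# calendar origin so offsets are easy to read

day0 <- as.Date("2021-03-01")
d <- function(k) day0 + k

mk_adm <- function(admission_id, admit, discharge,
                   patient_id = paste0("pt_", admission_id)) {
  tibble::tibble(patient_id = patient_id, admission_id = admission_id,
                 admit_date = d(admit), discharge_date = d(discharge))
}

mk_rx <- function(admission_id, drug_code, days, prescriber_id = "DR001",
                  patient_id = paste0("pt_", admission_id)) {
  tibble::tibble(patient_id = patient_id, admission_id = admission_id,
                 drug_code = drug_code, prescriber_id = prescriber_id,
                 admin_date = d(days))
}

mk_lab <- function(admission_id, value, days, analyte = "potassium",
                   order_days = days,
                   patient_id = paste0("pt_", admission_id)) {
  tibble::tibble(patient_id = patient_id, admission_id = admission_id,
                 analyte = analyte, value = as.character(value),
                 order_date = d(order_days), result_date = d(days))
}

mk_dx <- function(patient_id, icd10_code) {
  tibble::tibble(patient_id = patient_id, icd10_code = icd10_code)
}

quiet_cohort <- function(...) {
  suppressMessages(cohort_data(...))
}

# a small admission with daily potassium labs, long enough for eligible
# windows: admitted day 0, discharged day `len - 1`
lab_series <- function(admission_id, values, analyte = "potassium") {
  mk_lab(admission_id, values, seq_along(values) - 1, analyte = analyte)
}
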