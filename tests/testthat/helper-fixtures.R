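# in-code fixture builders

rx_tbl <- function(patient_id = "p1", practice_id = "pr1", atc = "R03BA02",
                   issue_date = "2016-01-01", quantity = 60,
                   doses_per_day = 2, strength_mg = NA_real_,
                   strength_ug = 200, linked_icpc = NA_character_,
                   tapering = NA) {
  tibble::tibble(
    patient_id = patient_id, practice_id = practice_id, atc = atc,
    issue_date = as.Date(issue_date), quantity = as.numeric(quantity),
    doses_per_day = as.numeric(doses_per_day),
    strength_mg = as.numeric(strength_mg),
    strength_ug = as.numeric(strength_ug),
    linked_icpc = linked_icpc, tapering = as.logical(tapering)
  )
}

patients_tbl <- function(patient_id = "p1", practice_id = "pr1",
                         birth_year = 1976L, sex = "female",
                         registered_from = "2014-01-01") {
  tibble::tibble(
    patient_id = patient_id, practice_id = practice_id,
    birth_year = as.integer(birth_year), sex = sex,
    registered_from = as.Date(registered_from), registered_to = as.Date(NA)
  )
}

episodes_tbl <- function(patient_id = "p1", icpc = "R96",
                         start_date = "2010-06-01", end_date = NA) {
  tibble::tibble(
    patient_id = patient_id, icpc = icpc,
    start_date = as.Date(start_date), end_date = as.Date(end_date)
  )
}

acq_tbl <- function(patient_id = "p1", date = "2016-06-01",
                    items = c(1, 1, 1, 1, 1), item6 = 2, item7 = NA) {
  tibble::tibble(
    patient_id = patient_id, date = as.Date(date),
    item1 = items[1], item2 = items[2], item3 = items[3],
    item4 = items[4], item5 = items[5],
    item6 = as.numeric(item6), item7 = as.numeric(item7)
  )
}
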