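#' @importFrom rlang .data
NULL

#' Build the per-patient analysis dataset
#'
#' Runs the whole derivation chain over the four input tables: cohort
#' selection, exclusion of patients with uncomputable ICS durations, CMA7
#' adherence over the pooled ICS stream, SABA counts, OCS-course
#' exacerbations, ACQ-5 control status, and the model covariates (age group,
#' comedication, comorbidity, GINA class). Patients without ICS-containing
#' prescriptions (GINA class 1) carry `NA` adherence and are excluded from
#' the outcome models downstream.
#'
#' @param tables List with `patients`, `episodes`, `prescriptions`, `acq`.
#' @param window An [observation_window()] (default: calendar 2016).
#' @param lookback_start Start of the pre-window carry-over lookback.
#' @param config Code-list configuration.
#' @param practice_profiles Optional practice-profile tibble; when given,
#'   [filter_practices()] restricts the registry first.
#' @return List: `data` (one row per analysed patient), `attrition`
#'   (flowchart counts through every step), `excluded_uncomputable` (the
#'   members dropped for uncomputable ICS duration).
#' @export
build_analysis_dataset <- function(tables, window = window_2016(),
                                   lookback_start = as.Date("2015-01-01"),
                                   config = code_config(),
                                   practice_profiles = NULL) {
  patients <- tables$patients
  attrition <- tibble::tibble(step = character(0), n_remaining = integer(0))
  if (!is.null(practice_profiles)) {
    pf <- filter_practices(practice_profiles)
    patients <- patients[patients$practice_id %in% pf$eligible, , drop = FALSE]
    attrition <- dplyr::bind_rows(
      attrition,
      tibble::tibble(step = "practice_quality_filter", n_remaining = nrow(patients)))
  }
  prescriptions <- tables$prescriptions[
    tables$prescriptions$patient_id %in% patients$patient_id, , drop = FALSE]

  sel <- select_patients(patients, tables$episodes, prescriptions, window)
  attrition <- dplyr::bind_rows(attrition, sel$attrition)

  part <- exclude_uncomputable_adherence(sel$members, prescriptions, window, config)
  cohort <- part$retained
  attrition <- dplyr::bind_rows(
    attrition,
    tibble::tibble(step = "computable_ics_duration", n_remaining = nrow(cohort)))

  ids <- cohort$patient_id
  rx <- prescriptions[prescriptions$patient_id %in% ids, , drop = FALSE]
  eps <- tables$episodes[tables$episodes$patient_id %in% ids, , drop = FALSE]
  acq <- tables$acq[tables$acq$patient_id %in% ids, , drop = FALSE]

  adherence <- cma7_by_patient(rx, ids, window, lookback_start, config)
  saba <- count_saba(rx, ids, window, config)
  exac <- derive_exacerbations(rx, ids, window, config = config)
  control <- derive_control(acq, ids, window)
  comed <- comedication_category(rx, ids, window, config)
  comorb <- comorbidity_category(eps, ids, window, config)
  gina <- gina_step(rx, ids, window, config)

  reg <- patients[match(ids, patients$patient_id), , drop = FALSE]
  data <- tibble::tibble(
    patient_id = ids,
    practice_id = cohort$practice_id,
    age = cohort$age_in_window,
    age_group = age_group(cohort$age_in_window),
    sex = factor(reg$sex, levels = c("male", "female"))
  ) |>
    dplyr::left_join(dplyr::rename(adherence, adherence_cat = "category"),
                     by = "patient_id") |>
    dplyr::left_join(saba, by = "patient_id") |>
    dplyr::left_join(exac, by = "patient_id") |>
    dplyr::left_join(control, by = "patient_id") |>
    dplyr::left_join(comed, by = "patient_id") |>
    dplyr::left_join(comorb, by = "patient_id") |>
    dplyr::left_join(gina, by = "patient_id")

  list(data = data, attrition = attrition, excluded_uncomputable = part$excluded)
}

#' Write the four tables of a generated EHR to a directory
#'
#' @param ehr Result of [generate_ehr()].
#' @param dir Output directory (created if needed).
#' @param write_truth Also write the ground-truth tables.
#' @return `dir`, invisibly.
#' @export
write_ehr <- function(ehr, dir, write_truth = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ehr_table(ehr$patients, file.path(dir, "patients.csv"))
  write_ehr_table(ehr$episodes, file.path(dir, "episodes.csv"))
  write_ehr_table(ehr$prescriptions, file.path(dir, "prescriptions.csv"))
  write_ehr_table(ehr$acq, file.path(dir, "acq.csv"))
  if (write_truth) {
    readr::write_csv(ehr$truth, file.path(dir, "ground_truth.csv"), na = "")
    readr::write_csv(ehr$practices, file.path(dir, "practices.csv"), na = "")
  }
  invisible(dir)
}

#' Read the four tables of an EHR directory
#'
#' @param dir Directory holding `patients.csv`, `episodes.csv`,
#'   `prescriptions.csv`, `acq.csv`.
#' @return List of the four validated tables.
#' @export
read_ehr <- function(dir) {
  list(
    patients = read_ehr_table(file.path(dir, "patients.csv"), "patients"),
    episodes = read_ehr_table(file.path(dir, "episodes.csv"), "episodes"),
    prescriptions = read_ehr_table(file.path(dir, "prescriptions.csv"), "prescriptions"),
    acq = read_ehr_table(file.path(dir, "acq.csv"), "acq")
  )
}
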