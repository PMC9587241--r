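age_levels <- c("12-17", "18-39", "40-54", "55-64", "65+")
count_levels <- c("0", "1", "2", ">2")
gina_levels <- c("1", "2", "3", "4", "5")

#' Age group
#'
#' Closed integer bins 12-17, 18-39, 40-54, 55-64, 65+ on the age attained
#' in the study year.
#'
#' @param age Integer ages, all at least 12 (cohort guarantee).
#' @return Factor with the five age levels.
#' @export
age_group <- function(age) {
  if (any(!is.na(age) & age < 12)) abort("age below 12 violates the cohort criterion")
  cut(age, breaks = c(-Inf, 17, 39, 54, 64, Inf), labels = age_levels)
}

count_category <- function(n) {
  cut(n, breaks = c(-Inf, 0, 1, 2, Inf), labels = count_levels)
}

#' Chronic comedication category
#'
#' Counts *distinct* ATC level-5 codes from the configured chronic-medication
#' list prescribed inside the window (repeat prescriptions of one drug count
#' once), grouped 0 / 1 / 2 / >2.
#'
#' @param prescriptions Prescription tibble.
#' @param patient_ids Patients to evaluate.
#' @param window An [observation_window()].
#' @param config Code-list configuration (uses `comedication_atc`).
#' @return Tibble: `patient_id`, `comed_n`, `comed_cat`.
#' @export
comedication_category <- function(prescriptions, patient_ids = NULL, window,
                                  config = code_config()) {
  patient_ids <- patient_ids %||% unique(prescriptions$patient_id)
  hits <- prescriptions[prescriptions$atc %in% config$comedication_atc &
                          in_window(prescriptions$issue_date, window), ,
                        drop = FALSE]
  hits <- dplyr::distinct(hits, .data$patient_id, .data$atc)
  n <- table(factor(hits$patient_id, levels = patient_ids))
  tibble::tibble(patient_id = patient_ids,
                 comed_n = as.integer(n[patient_ids]),
                 comed_cat = count_category(as.integer(n[patient_ids])))
}

#' Chronic comorbidity category
#'
#' Counts distinct ICPC codes from the configured chronic-illness list
#' (asthma R96 and COPD R95 excluded from that list) with an episode
#' starting on or before the window end: chronic conditions are treated as
#' ongoing. Grouped 0 / 1 / 2 / >2.
#'
#' @param episodes Diagnosis-episode tibble.
#' @param patient_ids Patients to evaluate.
#' @param window An [observation_window()].
#' @param config Code-list configuration (uses `comorbidity_icpc`).
#' @return Tibble: `patient_id`, `comorb_n`, `comorb_cat`.
#' @export
comorbidity_category <- function(episodes, patient_ids = NULL, window,
                                 config = code_config()) {
  patient_ids <- patient_ids %||% unique(episodes$patient_id)
  hits <- episodes[episodes$icpc %in% config$comorbidity_icpc &
                     episodes$start_date <= window$end, , drop = FALSE]
  hits <- dplyr::distinct(hits, .data$patient_id, .data$icpc)
  n <- table(factor(hits$patient_id, levels = patient_ids))
  tibble::tibble(patient_id = patient_ids,
                 comorb_n = as.integer(n[patient_ids]),
                 comorb_cat = count_category(as.integer(n[patient_ids])))
}

# step of one respiratory prescription given its drug class, daily ICS dose
# in ug and the dose-band table; NA when the step cannot be determined
rx_gina_step <- function(class, atc, daily_ug, has_separate_laba, config) {
  bands <- config$gina$dose_bands
  addon <- vapply(config$gina$addon_atc, function(p) startsWith(atc, p), TRUE)
  if (any(addon)) return(5L)
  if (class == "SABA") return(1L)
  if (class == "LAMA") return(5L)
  if (!is_ics_class(class)) return(NA_integer_)
  band <- bands[[atc]]
  if (is.null(band) || is.na(daily_ug)) return(NA_integer_)
  combo <- class == "ICS_LABA" || has_separate_laba
  if (daily_ug <= band$low_max) {
    if (combo) 3L else 2L
  } else {
    4L
  }
}

#' GINA 2016 treatment-step class
#'
#' Assigns each in-window respiratory prescription a treatment step
#' (SABA-only 1; low-dose ICS 2; low-dose ICS/LABA 3; medium/high-dose ICS
#' or ICS/LABA 4; add-on treatment such as LAMA or biologics 5) and
#' classifies the patient by the prescription with the highest step, i.e.
#' the highest ICS dose / treatment intensity of the year. ICS mono with a
#' separate LABA prescribed in the same window is treated like a fixed
#' combination. ICS prescriptions lacking `strength_ug` are step-undetermined;
#' a patient is undetermined (`NA`) only when every prescription is.
#'
#' @param prescriptions Prescription tibble.
#' @param patient_ids Patients to evaluate.
#' @param window An [observation_window()].
#' @param config Code-list configuration (uses `gina`).
#' @return Tibble: `patient_id`, `gina_class` (factor levels 1-5, `NA` when
#'   undetermined).
#' @export
gina_step <- function(prescriptions, patient_ids = NULL, window,
                      config = code_config()) {
  patient_ids <- patient_ids %||% unique(prescriptions$patient_id)
  resp <- prescriptions[in_window(prescriptions$issue_date, window), , drop = FALSE]
  addon_hit <- Reduce(`|`, lapply(config$gina$addon_atc,
                                  function(p) startsWith(resp$atc, p)),
                      accumulate = FALSE, init = rep(FALSE, nrow(resp)))
  resp <- resp[is_inhalation_rx(resp$atc) | addon_hit, , drop = FALSE]
  resp$class <- classify_atc(resp$atc, config)
  per <- split(resp, factor(resp$patient_id, levels = patient_ids))
  cls <- vapply(patient_ids, function(pid) {
    ev <- per[[pid]]
    if (is.null(ev) || nrow(ev) == 0L) return(NA_integer_)
    has_laba <- any(ev$class == "LABA")
    daily <- ev$strength_ug * ev$doses_per_day
    steps <- vapply(seq_len(nrow(ev)), function(i) {
      rx_gina_step(ev$class[i], ev$atc[i], daily[i], has_laba, config)
    }, integer(1))
    if (all(is.na(steps))) NA_integer_ else max(steps, na.rm = TRUE)
  }, integer(1))
  tibble::tibble(patient_id = patient_ids,
                 gina_class = factor(unname(cls), levels = 1:5,
                                     labels = gina_levels))
}
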