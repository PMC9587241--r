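#' Practice quality filter
#'
#' Keeps practices meeting the registration-quality criteria: a minimum
#' practice size, a minimum number of registration weeks per year, and
#' complete data over the surrounding study period. Emits per-criterion
#' attrition counts in filter order.
#'
#' @param profiles Tibble with one row per practice: `practice_id`,
#'   `n_patients`, `weeks_registered_per_year`, `data_complete`.
#' @param min_patients Minimum practice size (default 500).
#' @param min_weeks Minimum registration weeks per year (default 46).
#' @param require_complete Require complete study-period data (default TRUE).
#' @return List: `eligible` (practice ids), `attrition` (tibble of counts
#'   remaining after each criterion).
#' @export
filter_practices <- function(profiles, min_patients = 500L, min_weeks = 46L,
                             require_complete = TRUE) {
  if (anyDuplicated(profiles$practice_id)) {
    abort("duplicate practice_id in practice profiles")
  }
  if (any(profiles$weeks_registered_per_year < 0 |
            profiles$weeks_registered_per_year > 53)) {
    abort("weeks_registered_per_year must lie in 0..53")
  }
  steps <- list(
    size = profiles$n_patients >= min_patients,
    registration_weeks = profiles$weeks_registered_per_year >= min_weeks,
    complete_data = if (require_complete) profiles$data_complete else TRUE
  )
  keep <- rep(TRUE, nrow(profiles))
  attrition <- tibble::tibble(step = "all_practices", n_remaining = nrow(profiles))
  for (nm in names(steps)) {
    keep <- keep & steps[[nm]]
    attrition <- dplyr::bind_rows(
      attrition, tibble::tibble(step = nm, n_remaining = sum(keep)))
  }
  list(eligible = profiles$practice_id[keep], attrition = attrition)
}

#' Select the asthma cohort
#'
#' Applies the patient inclusion and exclusion rules: an asthma diagnosis
#' (ICPC R96 episode starting on or before the window end, or overlapping
#' the window under `asthma_rule = "active"`), age in the study year of at
#' least 12 (window start year minus birth year), at least two inhalation
#' prescriptions (ATC R03A/R03B) issued inside the window, and no COPD
#' (ICPC R95) episode overlapping the window. Open-ended episodes are
#' treated as ongoing. Attrition counts are reported in flowchart order.
#'
#' @param patients Registry tibble.
#' @param episodes Diagnosis-episode tibble.
#' @param prescriptions Prescription tibble.
#' @param window An [observation_window()].
#' @param asthma_rule `"on_or_before_end"` (default: prevalent or incident
#'   asthma) or `"active"` (episode must overlap the window).
#' @return List: `members` (tibble with per-rule flags, `exclusion_reason`,
#'   `member`), `attrition` (tibble of counts).
#' @export
select_patients <- function(patients, episodes, prescriptions, window,
                            asthma_rule = c("on_or_before_end", "active")) {
  asthma_rule <- match.arg(asthma_rule)
  orphan <- setdiff(prescriptions$patient_id, patients$patient_id)
  if (length(orphan) > 0L) {
    abort(sprintf("prescriptions reference %d patient(s) absent from the registry (e.g. %s)",
                  length(orphan), orphan[1]))
  }
  window_year <- as.integer(format(window$start, "%Y"))
  age <- window_year - patients$birth_year

  overlaps <- function(ep) {
    ep$start_date <= window$end & (is.na(ep$end_date) | ep$end_date >= window$start)
  }
  r96 <- episodes[episodes$icpc == "R96", , drop = FALSE]
  r96_ok_ids <- if (asthma_rule == "active") {
    unique(r96$patient_id[overlaps(r96)])
  } else {
    unique(r96$patient_id[r96$start_date <= window$end])
  }
  r95 <- episodes[episodes$icpc == "R95", , drop = FALSE]
  r95_ids <- unique(r95$patient_id[overlaps(r95)])

  inh <- prescriptions[is_inhalation_rx(prescriptions$atc) &
                         in_window(prescriptions$issue_date, window), , drop = FALSE]
  inh_n <- table(factor(inh$patient_id, levels = patients$patient_id))

  members <- tibble::tibble(
    patient_id = patients$patient_id,
    practice_id = patients$practice_id,
    age_in_window = age,
    has_asthma = patients$patient_id %in% r96_ok_ids,
    age_ok = age >= 12,
    enough_inhalation_rx = as.integer(inh_n[patients$patient_id]) >= 2L,
    no_copd = !patients$patient_id %in% r95_ids
  )
  rules <- c("has_asthma", "age_ok", "enough_inhalation_rx", "no_copd")
  reason <- rep(NA_character_, nrow(members))
  for (nm in rev(rules)) reason[!members[[nm]]] <- nm
  members$exclusion_reason <- reason
  members$member <- is.na(reason)

  keep <- rep(TRUE, nrow(members))
  attrition <- tibble::tibble(step = "registered_patients", n_remaining = nrow(members))
  for (nm in rules) {
    keep <- keep & members[[nm]]
    attrition <- dplyr::bind_rows(
      attrition, tibble::tibble(step = nm, n_remaining = sum(keep)))
  }
  list(members = members, attrition = attrition)
}

#' Exclude patients with uncomputable ICS prescription duration
#'
#' A cohort member is excluded when any ICS-containing prescription (ICS
#' mono or fixed ICS/LABA) issued inside the window lacks `quantity` or
#' `doses_per_day`, so that its duration cannot be calculated. The rule
#' applies to ICS-containing prescriptions only; missing dose fields on,
#' say, SABA prescriptions do not exclude. Both partitions are returned so
#' retained and excluded patients can be compared.
#'
#' @param members Cohort-member tibble (rows with `member = TRUE` are
#'   evaluated; others pass through in `excluded`'s complement untouched).
#' @param prescriptions Prescription tibble.
#' @param window An [observation_window()].
#' @param config Code-list configuration.
#' @return List: `retained` and `excluded` member tibbles (a partition of
#'   the member rows of the input).
#' @export
exclude_uncomputable_adherence <- function(members, prescriptions, window,
                                           config = code_config()) {
  mem <- members[members$member, , drop = FALSE]
  ics <- prescriptions[is_ics_class(classify_atc(prescriptions$atc, config)) &
                         in_window(prescriptions$issue_date, window), ,
                       drop = FALSE]
  bad_ids <- unique(ics$patient_id[is.na(ics$quantity) | is.na(ics$doses_per_day)])
  excluded <- mem[mem$patient_id %in% bad_ids, , drop = FALSE]
  retained <- mem[!mem$patient_id %in% bad_ids, , drop = FALSE]
  list(retained = retained, excluded = excluded)
}
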