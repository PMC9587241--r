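saba_levels <- c("0", "1-2", "3-6", "7-12", ">=13")
exac_levels <- c("0", "1", "2", "3", ">=4")

#' SABA prescription count category
#'
#' Five categories following GINA-derived use bands: 0, 1-2, 3-6, 7-12, and
#' 13 or more prescriptions per year.
#'
#' @param n Non-negative integer counts.
#' @return Factor with the five SABA levels.
#' @export
saba_category <- function(n) {
  if (any(!is.na(n) & (n < 0 | n != round(n)))) {
    abort("SABA counts must be non-negative integers")
  }
  cut(n, breaks = c(-Inf, 0, 2, 6, 12, Inf), labels = saba_levels)
}

#' Count SABA prescriptions per patient
#'
#' Counts in-window prescriptions classified SABA (salbutamol R03AC02,
#' terbutaline R03AC03) and maps the count to its category.
#'
#' @param prescriptions Prescription tibble.
#' @param patient_ids Patients to evaluate (default: all in the table).
#' @param window An [observation_window()].
#' @param config Code-list configuration.
#' @return Tibble: `patient_id`, `saba_n`, `saba_cat`.
#' @export
count_saba <- function(prescriptions, patient_ids = NULL, window,
                       config = code_config()) {
  patient_ids <- patient_ids %||% unique(prescriptions$patient_id)
  saba <- prescriptions[classify_atc(prescriptions$atc, config) == "SABA" &
                          in_window(prescriptions$issue_date, window), ,
                        drop = FALSE]
  n <- table(factor(saba$patient_id, levels = patient_ids))
  tibble::tibble(patient_id = patient_ids,
                 saba_n = as.integer(n[patient_ids]),
                 saba_cat = saba_category(as.integer(n[patient_ids])))
}

#' Which OCS prescriptions qualify as exacerbation treatment?
#'
#' A prednisolone/prednisone prescription qualifies when its daily dose
#' (`strength_mg * doses_per_day`) is at least `min_daily_mg` (default
#' 20 mg) or a tapering scheme was given, *and* the diagnosis rule holds:
#' either the linked ICPC code is respiratory (R chapter) other than COPD
#' (R95), or the prescription is unlinked and none of the patient's OCS
#' prescriptions carries a linked non-respiratory (or R95) diagnosis.
#' Prescriptions with no dose fields and no tapering flag do not qualify
#' (warned).
#'
#' @param ocs_events Tibble of one patient's OCS-class prescriptions.
#' @param min_daily_mg Daily-dose threshold in mg.
#' @return Logical vector over `ocs_events` rows.
#' @export
qualify_ocs <- function(ocs_events, min_daily_mg = 20) {
  if (nrow(ocs_events) == 0L) return(logical(0))
  daily <- ocs_events$strength_mg * ocs_events$doses_per_day
  taper <- !is.na(ocs_events$tapering) & ocs_events$tapering
  no_dose_info <- is.na(daily) & !taper
  if (any(no_dose_info)) {
    warn(sprintf("%d OCS prescription(s) without dose fields or tapering flag: non-qualifying",
                 sum(no_dose_info)))
  }
  dose_ok <- (!is.na(daily) & daily >= min_daily_mg) | taper
  linked <- ocs_events$linked_icpc
  respiratory <- !is.na(linked) & startsWith(linked, "R") & linked != "R95"
  other_dx <- !is.na(linked) & !respiratory
  # an unlinked prescription inherits eligibility only if the patient has no
  # OCS prescription linked to a non-respiratory (or COPD) diagnosis
  unlinked_ok <- is.na(linked) & !any(other_dx)
  dose_ok & (respiratory | unlinked_ok)
}

#' Merge qualifying OCS prescriptions into courses
#'
#' Prescriptions issued within 14 days belong to one OCS course; merging is
#' chained (transitive): a prescription joins the current course when its
#' date is at most `gap_days` after the previous prescription, otherwise it
#' starts a new course. The result does not depend on input order.
#'
#' @param issue_dates Dates of qualifying OCS prescriptions.
#' @param gap_days Maximum within-course date difference (default 14).
#' @return Tibble of courses: `course`, `start_date`, `end_date`, `n_rx`.
#' @export
build_ocs_courses <- function(issue_dates, gap_days = 14L) {
  if (length(issue_dates) == 0L) {
    return(tibble::tibble(course = integer(0), start_date = as.Date(character(0)),
                          end_date = as.Date(character(0)), n_rx = integer(0)))
  }
  d <- sort(as_ymd(issue_dates))
  new_course <- c(TRUE, diff(as.integer(d)) > gap_days)
  id <- cumsum(new_course)
  tibble::tibble(
    course = seq_len(max(id)),
    start_date = as.Date(tapply(d, id, min), origin = "1970-01-01"),
    end_date = as.Date(tapply(d, id, max), origin = "1970-01-01"),
    n_rx = as.integer(tapply(d, id, length))
  )
}

#' Derive OCS-course exacerbations per patient
#'
#' Filters in-window OCS prescriptions, applies the qualification rule,
#' merges qualifying prescriptions into courses, and summarises the count
#' into the categories 0, 1, 2, 3, >=4.
#'
#' @param prescriptions Prescription tibble.
#' @param patient_ids Patients to evaluate (default: all in the table).
#' @param window An [observation_window()].
#' @param gap_days Course merge gap in days (default 14).
#' @param min_daily_mg Daily-dose threshold in mg (default 20).
#' @param config Code-list configuration.
#' @return Tibble: `patient_id`, `n_courses`, `exac_cat`, `any_exacerbation`.
#' @export
derive_exacerbations <- function(prescriptions, patient_ids = NULL, window,
                                 gap_days = 14L, min_daily_mg = 20,
                                 config = code_config()) {
  patient_ids <- patient_ids %||% unique(prescriptions$patient_id)
  ocs <- prescriptions[classify_atc(prescriptions$atc, config) == "OCS" &
                         in_window(prescriptions$issue_date, window), ,
                       drop = FALSE]
  per <- split(ocs, factor(ocs$patient_id, levels = patient_ids))
  n_courses <- vapply(patient_ids, function(pid) {
    ev <- per[[pid]]
    if (is.null(ev) || nrow(ev) == 0L) return(0L)
    ok <- qualify_ocs(ev, min_daily_mg)
    nrow(build_ocs_courses(ev$issue_date[ok], gap_days))
  }, integer(1))
  tibble::tibble(
    patient_id = patient_ids,
    n_courses = unname(n_courses),
    exac_cat = cut(unname(n_courses), breaks = c(-Inf, 0, 1, 2, 3, Inf),
                   labels = exac_levels),
    any_exacerbation = unname(n_courses) >= 1L
  )
}

#' Select the ACQ record for the study year
#'
#' The last record dated inside the window is used; when none exists, the
#' earliest record in the first quarter of the following year; otherwise no
#' record. Ties on the selected date break towards the later row of the
#' input (stable order).
#'
#' @param records Tibble of one patient's ACQ records.
#' @param window An [observation_window()].
#' @return A one-row tibble, or `NULL` when no record is eligible.
#' @export
select_acq_record <- function(records, window) {
  if (is.null(records) || nrow(records) == 0L) return(NULL)
  inw <- records[in_window(records$date, window), , drop = FALSE]
  if (nrow(inw) > 0L) {
    pick <- max(which(inw$date == max(inw$date)))
    return(inw[pick, , drop = FALSE])
  }
  q1 <- next_q1(window)
  fq <- records[in_window(records$date, q1), , drop = FALSE]
  if (nrow(fq) > 0L) {
    pick <- max(which(fq$date == min(fq$date)))
    return(fq[pick, , drop = FALSE])
  }
  NULL
}

#' ACQ-5 score and control status
#'
#' Aggregates the first five ACQ items (symptom questions; the reliever-use
#' and FEV1 items are left out). The default aggregation is the item mean,
#' which keeps the score on the 0-6 per-item scale where the 0.75 control
#' cut-point is defined; `mode = "sum"` is available for sensitivity
#' analysis. Controlled asthma is a score strictly below `cutpoint`.
#'
#' @param record One ACQ record (one-row tibble with `item1`..`item5`).
#' @param mode `"mean"` (default) or `"sum"`.
#' @param cutpoint Control cut-point on the per-item scale (default 0.75).
#' @return List: `acq5`, `controlled`.
#' @export
acq5_score <- function(record, mode = c("mean", "sum"), cutpoint = 0.75) {
  mode <- match.arg(mode)
  items <- as.numeric(record[1, paste0("item", 1:5)])
  if (anyNA(items)) abort("ACQ record with a missing item among the first five is unusable")
  score <- if (mode == "mean") mean(items) else sum(items)
  threshold <- if (mode == "mean") cutpoint else cutpoint * 5
  list(acq5 = score, controlled = score < threshold)
}

#' Derive self-reported asthma control per patient
#'
#' Applies [select_acq_record()] and [acq5_score()] per patient.
#'
#' @param acq ACQ record tibble (multiple patients).
#' @param patient_ids Patients to evaluate.
#' @param window An [observation_window()].
#' @param mode Aggregation mode for [acq5_score()].
#' @return Tibble: `patient_id`, `acq_available`, `acq5`, `acq_date`,
#'   `controlled`.
#' @export
derive_control <- function(acq, patient_ids = NULL, window,
                           mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  patient_ids <- patient_ids %||% unique(acq$patient_id)
  per <- split(acq, factor(acq$patient_id, levels = patient_ids))
  rows <- purrr::map(patient_ids, function(pid) {
    sel <- select_acq_record(per[[pid]], window)
    if (is.null(sel)) {
      return(tibble::tibble(patient_id = pid, acq_available = FALSE,
                            acq5 = NA_real_, acq_date = as.Date(NA),
                            controlled = NA))
    }
    sc <- acq5_score(sel, mode)
    tibble::tibble(patient_id = pid, acq_available = TRUE, acq5 = sc$acq5,
                   acq_date = sel$date, controlled = sc$controlled)
  })
  dplyr::bind_rows(rows)
}
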