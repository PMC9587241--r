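#' Table schemas for routine-care extracts
#'
#' Four delimited tables feed the pipeline: `prescriptions` (one row per
#' issued prescription), `patients` (the registry), `episodes` (diagnosis
#' episodes) and `acq` (Asthma Control Questionnaire records, items 1-7).
#'
#' @param name One of `"prescriptions"`, `"patients"`, `"episodes"`, `"acq"`.
#' @return A schema description (column names, types, required flags).
#' @export
ehr_schema <- function(name = c("prescriptions", "patients", "episodes", "acq")) {
  name <- match.arg(name)
  col <- function(type, required = TRUE) list(type = type, required = required)
  cols <- switch(name,
    prescriptions = list(
      patient_id    = col("character"),
      practice_id   = col("character"),
      atc           = col("character"),
      issue_date    = col("date"),
      quantity      = col("number", required = FALSE),
      doses_per_day = col("number", required = FALSE),
      strength_mg   = col("number", required = FALSE),
      strength_ug   = col("number", required = FALSE),
      linked_icpc   = col("character", required = FALSE),
      tapering      = col("logical", required = FALSE)
    ),
    patients = list(
      patient_id      = col("character"),
      practice_id     = col("character"),
      birth_year      = col("number"),
      sex             = col("character"),
      registered_from = col("date"),
      registered_to   = col("date", required = FALSE)
    ),
    episodes = list(
      patient_id = col("character"),
      icpc       = col("character"),
      start_date = col("date"),
      end_date   = col("date", required = FALSE)
    ),
    acq = list(
      patient_id = col("character"),
      date       = col("date"),
      item1 = col("number"), item2 = col("number"), item3 = col("number"),
      item4 = col("number"), item5 = col("number"),
      item6 = col("number", required = FALSE),
      item7 = col("number", required = FALSE)
    )
  )
  structure(list(name = name, cols = cols), class = "ehr_schema")
}

parse_col <- function(x, type) {
  switch(type,
    character = {
      out <- as.character(x)
      out[!is.na(out) & !nzchar(trimws(out))] <- NA_character_
      out
    },
    number = suppressWarnings(as.numeric(x)),
    logical = {
      lx <- tolower(trimws(as.character(x)))
      out <- rep(NA, length(x))
      out[lx %in% c("true", "t", "1", "yes")] <- TRUE
      out[lx %in% c("false", "f", "0", "no")] <- FALSE
      out
    },
    date = suppressWarnings(as.Date(as.character(x), format = "%Y-%m-%d"))
  )
}

# per-row invariant checks; returns a character vector of violation messages
# (zero-length when the row set is clean), aligned with rows via names
row_violations <- function(df, schema) {
  msgs <- character(0)
  note <- function(rows, what) {
    if (any(rows, na.rm = TRUE)) {
      idx <- which(rows)
      msgs <<- c(msgs, setNames(rep(what, length(idx)), idx))
    }
    invisible(NULL)
  }
  for (nm in names(schema$cols)) {
    spec <- schema$cols[[nm]]
    x <- df[[nm]]
    if (spec$required) note(is.na(x), sprintf("missing or unparseable `%s`", nm))
  }
  if (schema$name == "prescriptions") {
    note(!is.na(df$atc) & !grepl(atc_grammar, df$atc), "malformed `atc`")
    for (nm in c("quantity", "doses_per_day", "strength_mg", "strength_ug")) {
      note(!is.na(df[[nm]]) & df[[nm]] <= 0, sprintf("non-positive `%s`", nm))
    }
  }
  if (schema$name == "patients") {
    note(!is.na(df$birth_year) &
           (df$birth_year < 1900 | df$birth_year > 2100 |
              df$birth_year != round(df$birth_year)),
         "implausible `birth_year`")
    note(!is.na(df$sex) & !df$sex %in% c("male", "female"),
         "`sex` must be male/female")
  }
  if (schema$name == "episodes") {
    note(!is.na(df$end_date) & !is.na(df$start_date) &
           df$end_date < df$start_date, "`end_date` precedes `start_date`")
  }
  if (schema$name == "acq") {
    for (nm in paste0("item", 1:7)) {
      note(!is.na(df[[nm]]) &
             (df[[nm]] < 0 | df[[nm]] > 6 | df[[nm]] != round(df[[nm]])),
           sprintf("`%s` outside ordinal range 0..6", nm))
    }
  }
  msgs
}

#' Read a routine-care extract table
#'
#' Reads a delimited file against one of the four schemas, coerces column
#' types, validates row-level invariants, and returns the clean records in
#' file order. Rows violating an invariant are dropped with a warning; the
#' rejected rows and their diagnostics are attached as attribute
#' `"rejected"` (a tibble with `line` and `problem` columns). Unknown extra
#' columns are ignored with a warning. A missing mandatory column is an
#' error naming the column.
#'
#' @param path File path.
#' @param schema Schema name or an [ehr_schema()] object.
#' @param delim Field delimiter (default comma).
#' @param col_map Optional named character vector mapping file header names
#'   onto schema field names, e.g. `c(pat = "patient_id")`.
#' @return A tibble of validated records.
#' @export
read_ehr_table <- function(path, schema, delim = ",", col_map = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.character(schema)) schema <- ehr_schema(schema)
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  if (!is.null(col_map)) {
    hit <- names(raw) %in% names(col_map)
    names(raw)[hit] <- unname(col_map[names(raw)[hit]])
  }
  wanted <- names(schema$cols)
  required <- wanted[vapply(schema$cols, `[[`, TRUE, "required")]
  absent <- setdiff(required, names(raw))
  if (length(absent) > 0L) {
    abort(sprintf("table `%s`: missing mandatory column(s): %s",
                  schema$name, paste(absent, collapse = ", ")))
  }
  extra <- setdiff(names(raw), wanted)
  if (length(extra) > 0L) {
    warn(sprintf("table `%s`: ignoring unknown column(s): %s",
                 schema$name, paste(extra, collapse = ", ")))
  }
  for (nm in setdiff(wanted, names(raw))) raw[[nm]] <- NA_character_
  df <- tibble::as_tibble(raw[wanted])
  for (nm in wanted) df[[nm]] <- parse_col(df[[nm]], schema$cols[[nm]]$type)
  msgs <- row_violations(df, schema)
  if (length(msgs) > 0L) {
    bad <- sort(unique(as.integer(names(msgs))))
    rejected <- tibble::tibble(
      line = as.integer(names(msgs)) + 1L,  # header is line 1
      problem = unname(msgs)
    )
    warn(sprintf("table `%s`: rejected %d row(s); first: line %d (%s)",
                 schema$name, length(bad), rejected$line[1], rejected$problem[1]))
    df <- df[-bad, , drop = FALSE]
    attr(df, "rejected") <- rejected
  } else {
    attr(df, "rejected") <- tibble::tibble(line = integer(0), problem = character(0))
  }
  df
}

#' Write a routine-care extract table
#'
#' Inverse of [read_ehr_table()]: dates are written as ISO-8601, logicals as
#' TRUE/FALSE, so a write/read round trip is lossless for all schema fields.
#'
#' @param df Tibble of records.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_ehr_table <- function(df, path, delim = ",") {
  readr::write_delim(df, path, delim = delim, na = "")
  invisible(path)
}
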