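#' Drug and diagnosis code lists
#'
#' Loads the code-list configuration: the ATC-prefix to drug-class map, the
#' chronic comedication ATC list, the chronic comorbidity ICPC list, and the
#' GINA dose bands. The shipped defaults are implementer-chosen and can be
#' replaced by pointing `path` at an edited YAML file.
#'
#' @param path Path to a YAML code-list file. Defaults to the file shipped
#'   with the package.
#' @return A list with elements `atc_classes`, `comedication_atc`,
#'   `comorbidity_icpc` and `gina`.
#' @export
code_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "code-lists.yaml",
                                package = "asthmaCMA", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  needed <- c("atc_classes", "comedication_atc", "comorbidity_icpc", "gina")
  missing <- setdiff(needed, names(cfg))
  if (length(missing) > 0L) {
    abort(sprintf("code-list config lacks field(s): %s",
                  paste(missing, collapse = ", ")))
  }
  cfg
}

#' Drug classes recognised by the pipeline
#' @export
drug_classes <- function() {
  c("SABA", "ICS", "LABA", "ICS_LABA", "LAMA", "OCS", "OTHER_R03", "NON_RESP")
}

atc_grammar <- "^[A-Z][0-9]{2}[A-Z]{0,2}[0-9]{0,2}$"

#' Classify ATC codes into drug classes
#'
#' Longest-prefix match of each ATC code against the configured class map.
#' Codes matching no configured prefix classify as `NON_RESP`. Classification
#' is total and deterministic on well-formed codes.
#'
#' @param atc Character vector of ATC codes (level 5, or any prefix of at
#'   least level 2 such as `"R03"`).
#' @param config Code-list configuration, see [code_config()].
#' @return Character vector of drug classes, same length as `atc`.
#' @examples
#' \dontrun{
#' classify_atc(c("R03AC02", "H02AB06", "N02BE01"))
#' }
#' @export
classify_atc <- function(atc, config = code_config()) {
  if (length(atc) == 0L) return(character(0))
  if (any(is.na(atc)) || any(!nzchar(atc))) {
    abort("ATC codes must be non-empty and non-missing")
  }
  bad <- !grepl(atc_grammar, atc)
  if (any(bad)) {
    abort(sprintf("malformed ATC code(s): %s",
                  paste(unique(head(atc[bad], 3L)), collapse = ", ")))
  }
  map <- config$atc_classes
  prefixes <- unlist(map, use.names = FALSE)
  classes <- rep(names(map), lengths(map))
  # longest prefix wins, so order candidate prefixes by decreasing length
  ord <- order(nchar(prefixes), decreasing = TRUE)
  prefixes <- prefixes[ord]
  classes <- classes[ord]
  out <- rep("NON_RESP", length(atc))
  unresolved <- rep(TRUE, length(atc))
  for (i in seq_along(prefixes)) {
    hit <- unresolved & startsWith(atc, prefixes[i])
    out[hit] <- classes[i]
    unresolved[hit] <- FALSE
  }
  out
}

#' Is a prescription inhalation medication?
#'
#' True for ATC group R03A (adrenergic inhalants) and R03B (other inhalants:
#' glucocorticoids and anticholinergics); the cohort entry criterion counts
#' these prescriptions.
#'
#' @param atc Character vector of ATC codes.
#' @return Logical vector.
#' @export
is_inhalation_rx <- function(atc) {
  startsWith(atc, "R03A") | startsWith(atc, "R03B")
}

#' Does a drug class contain ICS?
#' @param class Character vector of drug classes.
#' @return Logical vector, `TRUE` for ICS mono and fixed ICS/LABA combinations.
#' @export
is_ics_class <- function(class) {
  class %in% c("ICS", "ICS_LABA")
}
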