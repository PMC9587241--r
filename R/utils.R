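#' @importFrom rlang abort warn %||%
#' @importFrom stats plogis qnorm rbinom rnorm rpois runif setNames uniroot
#' @importFrom utils head
NULL

`%||%` <- rlang::`%||%`

# single day-granular date representation used everywhere: base Date
as_ymd <- function(x) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(x, format = "%Y-%m-%d")
  if (anyNA(out) && !anyNA(x)) {
    abort(sprintf("unparseable ISO-8601 date(s): %s",
                  paste(head(x[is.na(out)], 3L), collapse = ", ")))
  }
  out
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number", name))
  }
  invisible(x)
}
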