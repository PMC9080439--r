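#' @useDynLib amrtriage, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats predict rpois runif setNames
#' @importFrom utils head read.csv write.csv
NULL

# Classed conditions so callers and tests can discriminate failure modes.
abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "amrtriage_error")))
}

abort_validation <- function(msg, ...) abort(msg, "amrtriage_validation", ...)
abort_parse      <- function(msg, ...) abort(msg, "amrtriage_parse", ...)
abort_state      <- function(msg, ...) abort(msg, "amrtriage_state", ...)

# Retrieval failures carry a retryable flag so batch drivers can re-attempt
# transport errors but not malformed requests.
abort_retrieval <- function(msg, retryable = TRUE, ...) {
  abort(msg, "amrtriage_retrieval", retryable = retryable, ...)
}

# Round half away from zero (3.5 -> 4), unlike base round()'s round-half-even.
# Metric tables are reported at 2 dp and percentages at 0 dp with this rule.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

check_doc_ids <- function(ids, what = "doc_id") {
  if (anyNA(ids) || any(!nzchar(ids))) {
    abort_validation(sprintf("empty or missing %s", what))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort_validation(sprintf(
      "duplicate %s: %s", what, paste(head(dup, 5), collapse = ", ")
    ))
  }
  invisible(ids)
}
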