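#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @useDynLib cogscreen, .registration = TRUE
NULL

abort_domain <- function(msg) stop(structure(
  class = c("cogscreen_domain_error", "error", "condition"),
  list(message = msg, call = sys.call(-1))
))

abort_validation <- function(msg) stop(structure(
  class = c("cogscreen_validation_error", "error", "condition"),
  list(message = msg, call = sys.call(-1))
))

stopifnot_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_domain(sprintf("`%s` must be a finite numeric scalar", name))
  invisible(x)
}

#' Canonicalize free-text answers before matching
#'
#' Lower-cases, strips punctuation and collapses whitespace. The same
#' canonicalization is used by every scorer and by the Jaro-Winkler
#' auxiliaries, so point rules and spelling features always see the
#' identical string.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
canonicalize_answer <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[[:punct:]]", "", x)
  gsub("[[:space:]]+", " ", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic per-purpose seed derived from a master seed; kept < 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2048L + (as.integer(offset) %% 2048L)
}
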