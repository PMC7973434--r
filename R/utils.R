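# Internal helpers shared across the package.

#' @keywords internal
#' @useDynLib sgascreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed errors so callers/tests can distinguish failure modes
stopf <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(errorCondition(msg, class = c(class, "sgascreen_error", "error", "condition"),
                      call = sys.call(-1)))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_count <- function(x, name) {
  if (!is_count(x)) stopf("sga_argument_error", "'%s' must be a positive integer", name)
  as.integer(x)
}

check_prob <- function(x, name, open_upper = FALSE) {
  ok <- is_number(x) && x >= 0 && (if (open_upper) x < 1 else x <= 1)
  if (!ok) stopf("sga_argument_error", "'%s' must be in [0, %s", name,
                 if (open_upper) "1)" else "1]")
  as.numeric(x)
}

# midpoint of a gene interval on the 0-based half-open convention
gene_midpoint <- function(genome) (genome$start + genome$end) / 2

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector, applied
#' within one family of tests (here: one contrast across genes). Thin
#' validated wrapper around the standard step-up procedure with
#' running-minimum enforcement and capping at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed; propagated).
#' @return numeric vector of adjusted p-values, elementwise >= `p`.
#' @export
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04))
adjust_bh <- function(p) {
  if (!is.numeric(p)) stopf("sga_argument_error", "p-values must be numeric")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stopf("sga_argument_error", "p-values outside [0,1] at position(s) %s",
          paste(which(bad)[seq_len(min(5, sum(bad)))], collapse = ", "))
  }
  stats::p.adjust(p, method = "BH")
}
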