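#' @useDynLib repforge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Biostrings
NULL

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors. `N` is its own
#' complement; input may be upper or lower case, output is upper case.
#'
#' @param x Character vector of DNA sequences (alphabet `A,C,G,T,N`).
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "AAN"))
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  revcomp_cpp(toupper(x))
}

#' Canonical form of a k-mer
#'
#' The lexicographic minimum of a k-mer and its reverse complement. Shotgun
#' reads sample both strands, so counting canonical k-mers makes the occurrence
#' spectrum strand-independent.
#'
#' @param x Character vector of k-mers.
#' @return Character vector of canonical k-mers.
#' @export
canonical_kmer <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

## internal: stop with a classed condition so tests can assert on error types
rf_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "repforge_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

## internal: check a single positive number
is_count1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0
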