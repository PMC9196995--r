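#' Reverse complement of a nucleotide string
#'
#' Case is folded to uppercase; characters outside ACGT become `N`.
#'
#' @param seq A single nucleotide string.
#' @return The reverse complement, uppercase.
#' @export
#' @examples
#' revcomp("acgT")
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  cpp_revcomp(seq)
}

assert_decreasing_ks <- function(ks) {
  if (length(ks) < 1L || any(ks < 1L)) {
    stop("at least one k >= 1 is required", call. = FALSE)
  }
  if (length(ks) > 1L && any(diff(ks) >= 0)) {
    stop("k-mer lengths must be passed in decreasing order", call. = FALSE)
  }
  invisible(as.integer(ks))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
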