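#' Canonical form of k-mers
#'
#' The canonical form is the lexicographically smaller of a k-mer and its
#' reverse complement, which makes Bloom filter membership strand-
#' insensitive. Input is case-folded; characters outside ACGT are an error.
#'
#' @param kmers Character vector of k-mers.
#' @return Character vector of canonical k-mers.
#' @export
#' @examples
#' canonical_kmer(c("ACGT", "TTTT"))
canonical_kmer <- function(kmers) {
  cpp_canonical(kmers)
}

#' Extract canonical k-mers from a sequence
#'
#' The sequence is uppercased first (soft-masking is metadata, not
#' sequence); windows containing any character outside ACGT (e.g. `N`) are
#' skipped rather than expanded.
#'
#' @param seq A single nucleotide string.
#' @param k k-mer length.
#' @return Character vector of canonical k-mers, one per valid window, in
#'   sequence order.
#' @export
extract_kmers <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1L, k >= 1L)
  cpp_iter_kmers(seq, as.integer(k))
}

#' Exact canonical k-mer spectrum of a read set
#'
#' Counts every canonical k-mer occurrence across the reads with an exact
#' hash map (no streaming estimation), and summarizes the multiplicity
#' histogram together with the cardinality statistics used for Bloom filter
#' sizing: `F0` (distinct k-mers), `F1` (total occurrences) and `f1`
#' (k-mers seen exactly once).
#'
#' @param reads Character vector of read sequences.
#' @param k k-mer length.
#' @return A `kmer_spectrum` object: list with `k`, `hist` (data.frame of
#'   `multiplicity` and `count`), `F0`, `F1`, `f1`.
#' @export
kmer_spectrum <- function(reads, k) {
  stopifnot(k >= 1L)
  res <- cpp_count_spectrum(as.character(reads), as.integer(k))
  structure(
    list(k = as.integer(k),
         hist = data.frame(multiplicity = res$multiplicity,
                           count = res$count),
         F0 = res$F0, F1 = res$F1, f1 = res$f1),
    class = "kmer_spectrum"
  )
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("k-mer spectrum (k=%d): F0=%s distinct, F1=%s total, f1=%s singletons\n",
              x$k, format(x$F0, big.mark = ","),
              format(x$F1, big.mark = ","), format(x$f1, big.mark = ",")))
  invisible(x)
}

#' Number of k-mers with multiplicity two or more
#'
#' The quantity `n = F0 - f1` that sizes the cascading Bloom filter: only
#' repeated k-mers are retained by the two-level construction, so singleton
#' (likely erroneous) k-mers are excluded from the element count.
#'
#' @param spec A `kmer_spectrum`, or any list with `F0` and `f1` fields.
#' @return `F0 - f1`.
#' @export
repeated_kmer_count <- function(spec) {
  stopifnot(!is.null(spec$F0), !is.null(spec$f1))
  spec$F0 - spec$f1
}

#' Write a k-mer histogram file
#'
#' Two-column tab-separated layout: `F1` and `F0` statistic lines followed
#' by one row per multiplicity, written to `<prefix>_k<k>.hist`.
#'
#' @param spec A `kmer_spectrum`.
#' @param dir Output directory.
#' @param prefix File name prefix (default `"freq"`).
#' @return The file path, invisibly.
#' @export
write_hist <- function(spec, dir = ".", prefix = "freq") {
  stopifnot(inherits(spec, "kmer_spectrum"))
  path <- file.path(dir, sprintf("%s_k%d.hist", prefix, spec$k))
  lines <- c(sprintf("F1\t%.0f", spec$F1),
             sprintf("F0\t%.0f", spec$F0),
             sprintf("%.0f\t%.0f", spec$hist$multiplicity, spec$hist$count))
  writeLines(lines, path)
  invisible(path)
}

#' Read a k-mer histogram file back into a spectrum
#'
#' @param path Path to a `.hist` file written by [write_hist()].
#' @return A `kmer_spectrum` (the `k` is parsed from the file name when it
#'   matches the `_k<k>.hist` pattern, otherwise `NA`).
#' @export
read_hist <- function(path) {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  keys <- vapply(lines, `[`, "", 1L)
  vals <- as.numeric(vapply(lines, `[`, "", 2L))
  stat <- keys %in% c("F0", "F1")
  hist <- data.frame(multiplicity = as.numeric(keys[!stat]),
                     count = vals[!stat])
  k <- suppressWarnings(as.integer(sub("^.*_k(\\d+)\\.hist$", "\\1", path)))
  f1 <- if (any(hist$multiplicity == 1)) hist$count[hist$multiplicity == 1] else 0
  structure(list(k = k, hist = hist, F0 = vals[keys == "F0"],
                 F1 = vals[keys == "F1"], f1 = f1),
            class = "kmer_spectrum")
}
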