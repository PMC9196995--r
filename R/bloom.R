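#' Expected Bloom filter false positive rate
#'
#' For a filter of `m` bits holding `n` elements inserted with `h` hash
#' functions, the false positive rate is approximately
#' `(1 - exp(-h * n / m))^h`.
#'
#' @param m Filter size in bits (>= 1).
#' @param h Number of hash functions (>= 1).
#' @param n Number of inserted elements (>= 0).
#' @return Probability in `[0, 1)`.
#' @export
#' @examples
#' expected_fpr(1340826718, 1, 6720950)
expected_fpr <- function(m, h, n) {
  if (any(m < 1)) stop("m must be >= 1", call. = FALSE)
  if (any(h < 1)) stop("h must be >= 1", call. = FALSE)
  if (any(n < 0)) stop("n must be >= 0", call. = FALSE)
  (1 - exp(-h * n / m))^h
}

#' Optimal Bloom filter size in bits
#'
#' Inverts the false positive rate relation at `h = 1`:
#' `m = ceiling(-n / log(1 - f))`.
#'
#' @param n Expected number of distinct elements.
#' @param f Target false positive rate, in `(0, 1)`.
#' @return Size in bits (0 when `n = 0`).
#' @export
#' @examples
#' optimal_bits(6720950, 0.005)  # 1,340,826,718 bits
optimal_bits <- function(n, f) {
  if (any(f <= 0) || any(f >= 1)) stop("f must be in (0, 1)", call. = FALSE)
  if (any(n < 0)) stop("n must be >= 0", call. = FALSE)
  ceiling(-n / log(1 - f))
}

#' Bloom filter size in decimal megabytes
#'
#' @param m Size in bits.
#' @return `m / 8 / 1e6`, rounded to the nearest integer MB for reporting.
#' @export
#' @examples
#' bits_to_megabytes(1340826718)  # ~168 MB
bits_to_megabytes <- function(m) {
  if (any(m < 0)) stop("m must be >= 0", call. = FALSE)
  round(m / 8 / 1e6)
}

#' Parse a Bloom filter size with K/M/G suffix
#'
#' Sizes are decimal bytes (`"200M"` = 2e8 bytes) and are returned in bits.
#'
#' @param b A number of bytes, optionally suffixed with `K`, `M` or `G`
#'   (case-insensitive), as a string or plain number.
#' @return Size in bits.
#' @export
#' @examples
#' parse_bloom_size("200M")
parse_bloom_size <- function(b) {
  if (is.numeric(b)) return(b * 8)
  s <- toupper(trimws(b))
  m <- regmatches(s, regexec("^([0-9]*\\.?[0-9]+)([KMG]?)B?$", s))[[1]]
  if (length(m) == 0) stop("cannot parse Bloom filter size: '", b, "'",
                           call. = FALSE)
  mult <- c("1" = 1, K = 1e3, M = 1e6, G = 1e9)[[if (m[3] == "") "1" else m[3]]]
  as.numeric(m[2]) * mult * 8
}

#' Create an empty Bloom filter
#'
#' A bit-array membership set over canonical k-mers. Hashing is a seeded
#' 64-bit string hash, so two filters built with the same seed behave
#' identically across runs and platforms.
#'
#' @param m Size in bits.
#' @param k k-mer length the filter is built for.
#' @param h Number of hash functions (default 1, the sizing assumption).
#' @param seed Integer base seed for the hash family.
#' @return A `bloom_filter` object.
#' @export
bloom_filter <- function(m, k, h = 1L, seed = 13L) {
  ptr <- cpp_bloom_new(as.numeric(m), as.integer(h), as.integer(k),
                       as.numeric(seed))
  structure(list(ptr = ptr, m = as.numeric(m), h = as.integer(h),
                 k = as.integer(k), seed = as.numeric(seed)),
            class = "bloom_filter")
}

#' @export
print.bloom_filter <- function(x, ...) {
  info <- cpp_bloom_info(x$ptr)
  cat(sprintf(
    "Bloom filter: k=%d, m=%s bits (%d MB), h=%d, %s insertions, %s bits set\n",
    info$k, format(info$m, big.mark = ","), bits_to_megabytes(info$m),
    info$h, format(info$n_inserted, big.mark = ","),
    format(info$bits_set, big.mark = ",")))
  invisible(x)
}

#' Insert k-mers into a Bloom filter
#'
#' k-mers are canonicalized before hashing; after `bloom_insert(bf, x)`,
#' `bloom_contains(bf, x)` is guaranteed `TRUE` (no false negatives).
#'
#' @param bf A `bloom_filter`.
#' @param kmers Character vector of k-mers of length `bf$k`.
#' @return `bf`, invisibly (the filter is modified in place).
#' @export
bloom_insert <- function(bf, kmers) {
  stopifnot(inherits(bf, "bloom_filter"))
  cpp_bloom_insert(bf$ptr, kmers)
  invisible(bf)
}

#' Query k-mers against a Bloom filter
#'
#' @inheritParams bloom_insert
#' @return Logical vector; never mutates the filter.
#' @export
bloom_contains <- function(bf, kmers) {
  stopifnot(inherits(bf, "bloom_filter"))
  cpp_bloom_contains(bf$ptr, kmers)
}

#' Insert every k-mer of whole sequences into a Bloom filter
#'
#' Convenience builder (e.g. for a ground-truth filter): every valid
#' canonical k-mer of each sequence is inserted, regardless of multiplicity.
#'
#' @param bf A `bloom_filter`.
#' @param seqs Character vector of sequences.
#' @return `bf`, invisibly.
#' @export
bloom_insert_seqs <- function(bf, seqs) {
  stopifnot(inherits(bf, "bloom_filter"))
  cpp_bloom_insert_seqs(bf$ptr, as.character(seqs))
  invisible(bf)
}

#' Bloom filter summary statistics
#'
#' @param bf A `bloom_filter`.
#' @return List with `m`, `h`, `k`, `n_inserted` (insertion calls attempted)
#'   and `bits_set`.
#' @export
bloom_info <- function(bf) {
  stopifnot(inherits(bf, "bloom_filter"))
  cpp_bloom_info(bf$ptr)
}

#' Build a two-level cascading Bloom filter from reads
#'
#' Single pass over the read k-mers with two equal-size filters: an
#' occurrence whose k-mer is already present in level 1 is inserted into
#' level 2. Level 2 therefore contains every k-mer of true multiplicity two
#' or more (no false negatives for them) plus a bounded fraction of
#' singleton k-mers admitted by level-1 false positives. Singleton k-mers
#' are overwhelmingly sequencing errors, so the returned level-2 filter is
#' the error-filtered membership set the polisher and gap filler query.
#'
#' @param reads Character vector of read sequences.
#' @param k k-mer length.
#' @param m Size of each level in bits.
#' @param h Number of hash functions (default 1).
#' @param seed Hash seed (default 13).
#' @return The level-2 `bloom_filter`.
#' @export
build_cascading_filter <- function(reads, k, m, h = 1L, seed = 13L) {
  ptr <- cpp_build_cascading(as.character(reads), as.integer(k),
                             as.numeric(m), as.integer(h), as.numeric(seed))
  structure(list(ptr = ptr, m = as.numeric(m), h = as.integer(h),
                 k = as.integer(k), seed = as.numeric(seed)),
            class = "bloom_filter")
}

#' Size a Bloom filter from k-mer spectra
#'
#' Takes the repeated-k-mer count `n = F0 - f1` of each supplied spectrum,
#' keeps the largest (so the filter is adequate for every k in the sweep),
#' and sizes the filter at the target false positive rate.
#'
#' @param spectra A `kmer_spectrum` or list of them (one per sweep k).
#' @param f Target false positive rate (default 0.005).
#' @param h Hash count carried into the returned spec (default 1; the
#'   sizing formula assumes one hash function).
#' @return A `bloom_spec`: list with `n`, `f`, `m` (bits), `h` and `mb`.
#' @export
auto_size <- function(spectra, f = 0.005, h = 1L) {
  if (inherits(spectra, "kmer_spectrum")) spectra <- list(spectra)
  if (length(spectra) == 0) {
    stop("at least one k-mer spectrum is required", call. = FALSE)
  }
  n <- max(vapply(spectra, repeated_kmer_count, numeric(1)))
  m <- optimal_bits(n, f)
  structure(list(n = n, f = f, m = m, h = as.integer(h),
                 mb = bits_to_megabytes(m)),
            class = "bloom_spec")
}

#' @export
print.bloom_spec <- function(x, ...) {
  cat(sprintf("Bloom sizing: n=%s repeated k-mers, f=%g -> m=%s bits (~%d MB, h=%d)\n",
              format(x$n, big.mark = ","), x$f,
              format(x$m, big.mark = ","), x$mb, x$h))
  invisible(x)
}
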