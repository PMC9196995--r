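# Independent oracles, implemented with base R and Biostrings only. They
# never call the package's C++ core, so agreement between the two is
# evidence, not tautology.

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

oracle_canonical <- function(x) {
  x <- toupper(x)
  rc <- oracle_revcomp(x)
  ifelse(x <= rc, x, rc)
}

# all valid (ACGT-only, case-folded) k-mer windows of one sequence, in order
oracle_windows <- function(s, k) {
  s <- toupper(s)
  n <- nchar(s)
  if (n < k) return(character())
  w <- substring(s, seq_len(n - k + 1L), k:n)
  w[grepl("^[ACGT]+$", w)]
}

# exact canonical k-mer multiplicities of a read set
oracle_kmer_counts <- function(seqs, k) {
  kms <- unlist(lapply(seqs, oracle_windows, k = k), use.names = FALSE)
  if (length(kms) == 0) return(integer())
  tab <- table(oracle_canonical(kms))
  stats::setNames(as.integer(tab), names(tab))
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_kmers <- function(n, k, seed) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n * k, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

# Exhaustive depth-first search over an explicit canonical k-mer set,
# mirroring the traversal contract: start from the terminal k-mer of the
# left flank, extend by single bases (A explored first), succeed when the
# initial k-mer of the right flank is reached; the reported string is the
# extension minus the final k bases. No branch budget: fixtures are small.
oracle_dfs <- function(kmers, left, right, k, max_len, max_paths = 1e9) {
  set <- new.env(hash = TRUE, parent = emptyenv())
  for (km in unique(oracle_canonical(kmers))) assign(km, TRUE, envir = set)
  has <- function(km) exists(oracle_canonical(km), envir = set,
                             inherits = FALSE)
  left <- toupper(left)
  right <- toupper(right)
  start <- substr(left, nchar(left) - k + 1L, nchar(left))
  target <- substr(right, 1L, k)
  depth_cap <- max_len + k
  paths <- character()
  stack <- list(list(kmer = start, ext = ""))
  while (length(stack) > 0) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (nchar(fr$ext) >= depth_cap) next
    for (b in c("T", "G", "C", "A")) {  # pushed in reverse; A popped first
      nxt <- paste0(substr(fr$kmer, 2L, k), b)
      if (!has(nxt)) next
      ext <- paste0(fr$ext, b)
      if (nxt == target) {
        t <- nchar(ext)
        paths <- c(paths, if (t > k) substr(ext, 1L, t - k) else "")
        if (length(paths) >= max_paths) return(paths)
      } else {
        stack[[length(stack) + 1L]] <- list(kmer = nxt, ext = ext)
      }
    }
  }
  paths
}

# A filter with ~1e-6 false positive rate at modest memory: with one hash
# function that rate costs 1/f bits per element, but with h = 3 it needs
# m = -h*n / ln(1 - f^(1/3)) ~ 300 bits per element.
tight_bits <- function(n) {
  ceiling(-3 * n / log(1 - 1e-2))  # (1e-6)^(1/3) = 1e-2
}

tight_bloom <- function(n, k, seed = 13) {
  bloom_filter(tight_bits(n), k = k, h = 3, seed = seed)
}

# ground-truth k-mer membership filter over whole sequences
sequence_filter <- function(seqs, k) {
  bf <- tight_bloom(sum(nchar(seqs)), k)
  bloom_insert_seqs(bf, seqs)
  bf
}

# 1-based positions of lowercase characters
lowercase_positions <- function(s) {
  which(strsplit(s, "", fixed = TRUE)[[1]] %in% letters)
}
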