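# ground-truth filter: every k-mer of the genome, sized so false positives
# are negligible
truth_filter <- function(genome_seq, k) sequence_filter(genome_seq, k)

test_that("candidate enumeration is complete and deterministically ordered", {
  s <- random_dna(100, seed = 51)
  cands <- enumerate_edits(s, 50, max_indel = 5)
  # 3 substitutions + (4 + 16 + 64 + 256 + 1024) insertions + 5 deletions
  expect_identical(nrow(cands), 3L + 1364L + 5L)
  expect_identical(cands$kind,
                   c(rep("substitution", 3), rep("insertion", 1364),
                     rep("deletion", 5)))
  # substitutions preserve ACGT order and skip the current base
  cur <- substr(s, 51, 51)
  expect_identical(cands$alt[1:3], setdiff(c("A", "C", "G", "T"), cur))
  # insertions ordered by length then lexicographically
  ins <- cands$alt[cands$kind == "insertion"]
  expect_identical(ins[1:5], c("A", "C", "G", "T", "AA"))
  expect_identical(nchar(ins), rep(1:5, 4^(1:5)))
  expect_true(all(diff(match(ins[5:20], sort(ins[5:20]))) > 0))
  # deletions grow from the position rightward
  del <- cands[cands$kind == "deletion", ]
  expect_identical(del$ref, substring(s, 51, 51:55))
})

test_that("deletions are clipped at the contig end and stop at non-ACGT", {
  s <- paste0(random_dna(60, seed = 52), "AC")
  cands <- enumerate_edits(s, 60, max_indel = 5)
  expect_identical(sum(cands$kind == "deletion"), 2L)
  s2 <- paste0(random_dna(60, seed = 53), "AGN", "ACGT")
  cands2 <- enumerate_edits(s2, 60, max_indel = 5)
  expect_identical(sum(cands2$kind == "deletion"), 2L)  # stops before the N
})

test_that("the exact reverting edit has full support under a truth filter", {
  g <- random_dna(500, seed = 54)
  bf <- truth_filter(g, 31)
  draft <- g
  substr(draft, 250, 250) <- if (substr(g, 250, 250) == "A") "C" else "A"
  expect_equal(edit_support(draft, 249, substr(draft, 250, 250),
                            substr(g, 250, 250), bf), 1)
  # a wrong substitution recovers (almost) nothing
  wrong <- setdiff(c("A", "C", "G", "T"),
                   c(substr(draft, 250, 250), substr(g, 250, 250)))[1]
  expect_lt(edit_support(draft, 249, substr(draft, 250, 250), wrong, bf), 0.1)
})

test_that("a draft identical to the truth is left untouched", {
  g <- random_dna(2000, seed = 55)
  bf <- truth_filter(g, 40)
  res <- polish_contig(g, bf)
  expect_identical(res$contig$seq, g)
  expect_identical(nrow(res$edits), 0L)
  expect_equal(res$masked_bases, 0)
})

test_that("isolated substitutions, insertions and deletions are exactly reverted", {
  g <- random_dna(3000, seed = 56)
  bf <- truth_filter(g, 40)

  # substitution at 1500
  d1 <- g
  substr(d1, 1500, 1500) <- if (substr(g, 1500, 1500) == "G") "T" else "G"
  r1 <- polish_contig(d1, bf)
  expect_identical(r1$contig$seq, g)
  expect_identical(r1$edits$kind, "substitution")
  expect_equal(r1$edits$position, 1500)
  expect_equal(r1$edits$support, 1)

  # 3 nt insertion present in the draft at 1000 -> deletion edit
  d2 <- paste0(substr(g, 1, 999), "TAG", substr(g, 1000, nchar(g)))
  r2 <- polish_contig(d2, bf)
  expect_identical(r2$contig$seq, g)
  expect_identical(r2$edits$kind, "deletion")

  # 2 nt missing from the draft at 2000 -> insertion edit
  d3 <- paste0(substr(g, 1, 1999), substr(g, 2002, nchar(g)))
  r3 <- polish_contig(d3, bf)
  expect_identical(r3$contig$seq, g)
  expect_identical(r3$edits$kind, "insertion")
  expect_identical(r3$edits$alt, substr(g, 2000, 2001))
})

test_that("edit positions refer to the pre-edit contig of the iteration", {
  g <- random_dna(3000, seed = 57)
  bf <- truth_filter(g, 40)
  # a deletion-in-draft at 1000 shifts later coordinates by +2; the edit at
  # 2500 must still be recorded in draft coordinates
  draft <- paste0(substr(g, 1, 999), "CA", substr(g, 1000, nchar(g)))
  substr(draft, 2502, 2502) <-
    if (substr(draft, 2502, 2502) == "A") "C" else "A"
  res <- polish_contig(draft, bf)
  expect_identical(res$contig$seq, g)
  expect_equal(sort(res$edits$position), c(1000, 2502))
  # replaying the recorded edits reproduces the polished sequence
  expect_identical(apply_edits(draft, res$edits), g)
})

test_that("contigs shorter than k pass through unchanged", {
  bf <- bloom_filter(1e4, k = 40)
  res <- polish_contig("ACGTACGT", bf)
  expect_identical(res$contig$seq, "ACGTACGT")
  expect_identical(nrow(res$edits), 0L)
})

test_that("existing N and soft-masked characters are never edited", {
  g <- random_dna(2000, seed = 58)
  bf <- truth_filter(g, 40)
  draft <- g
  substr(draft, 1000, 1004) <- "NNNNN"
  masked <- paste0(substr(g, 1, 499), tolower(substr(g, 500, 519)),
                   substr(g, 520, nchar(g)))
  r1 <- polish_contig(draft, bf)
  expect_identical(substr(r1$contig$seq, 1000, 1004), "NNNNN")
  r2 <- polish_contig(masked, bf)
  expect_identical(r2$contig$seq, masked)
  expect_identical(nrow(r2$edits), 0L)
})

test_that("a scrambled stretch is soft-masked, with no edits inside", {
  g <- simulate_genome(20000, seed = 59)
  cor <- corrupt_genome(g, sub_rate = 0, indel_rate = 0, n_gaps = 0,
                        n_scrambles = 1, scramble_len = 300, seed = 60)
  bf <- truth_filter(g$seq, 40)
  res <- polish_contig(cor$draft$seq, bf)
  iv <- cor$truth$mask_intervals
  s <- iv$pos
  e <- iv$pos + nchar(iv$ref) - 1L
  stretch <- substr(res$contig$seq, s, e)
  expect_identical(stretch, tolower(stretch))
  expect_false(any(res$edits$position >= s & res$edits$position <= e))
  # sequence away from the scramble is untouched
  expect_identical(substr(res$contig$seq, 1, s - 41),
                   substr(g$seq, 1, s - 41))
})

test_that("random substitutions are reverted wherever read evidence exists", {
  # Standard single-k conditions: 100 kb truth, ~200 substitutions,
  # error-free 30x reads, k = 40. Seeds fixed up front, never revisited.
  g <- simulate_genome(1e5, seed = 7)
  cor <- corrupt_genome(g, sub_rate = 0.002, indel_rate = 0, n_gaps = 0,
                        seed = 8)
  reads_path <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(g, coverage = 30, read_len = 150, error_rate = 0, seed = 9,
                 path = reads_path)
  reads <- stream_reads(reads_path)
  k <- 40L
  bf <- build_cascading_filter(reads, k, optimal_bits(2e5, 0.005))
  res <- polish_contig(cor$draft$seq, bf)
  ev <- cor$truth$mutations
  L <- nchar(g$seq)

  pol <- toupper(res$contig$seq)
  reverted <- vapply(seq_len(nrow(ev)), function(t) {
    lo <- max(1L, ev$pos[t] - 25L)
    hi <- min(L, ev$pos[t] + 25L)
    grepl(substr(g$seq, lo, hi), pol, fixed = TRUE)
  }, logical(1))

  # Errors the filter can evidence: nearest neighbor at least k away and
  # clear of the contig-end coverage ramp (the terminal read-length bases,
  # whose k-mers cannot reach multiplicity 2 in uniformly drawn reads).
  gap_l <- c(Inf, diff(ev$pos))
  gap_r <- c(diff(ev$pos), Inf)
  evidenced <- gap_l >= k & gap_r >= k & ev$pos > 150 & ev$pos <= L - 150
  expect_gt(sum(evidenced), 150)
  expect_gte(mean(reverted[evidenced]), 0.95)

  # complete accounting: every miss is a close pair, a contig-end event, or
  # sits in/next to a soft-masked run handed to the gap filler
  misses <- which(!reverted)
  soft <- lowercase_positions(res$contig$seq)
  explained <- vapply(misses, function(t) {
    close_pair <- min(gap_l[t], gap_r[t]) < k
    at_end <- ev$pos[t] <= 150 || ev$pos[t] > L - 150 || ev$pos[t] <= k
    near_mask <- length(soft) > 0 && min(abs(soft - ev$pos[t])) <= k
    close_pair || at_end || near_mask
  }, logical(1))
  expect_true(all(explained))

  # away from masked runs and contig ends, every output k-mer is present
  up_runs <- gregexpr("[ACGT]+", res$contig$seq)[[1]]
  for (r in seq_along(up_runs)) {
    s <- up_runs[r] + k
    e <- up_runs[r] + attr(up_runs, "match.length")[r] - 1L - k
    if (e - s + 1L < k) next
    expect_true(all(bloom_contains(bf, extract_kmers(substr(pol, s, e), k))))
  }

  # accepted edits are overwhelmingly true reversions (spurious <= 1%)
  ed <- res$edits
  is_true_edit <- mapply(function(p, alt) {
    any(ev$pos == p & ev$ref == alt)
  }, ed$position, ed$alt)
  expect_lte(mean(!is_true_edit), 0.01)
})

test_that("sweep masks accumulate and change tables replay exactly", {
  g <- simulate_genome(20000, seed = 61)
  cor <- corrupt_genome(g, n_gaps = 0, seed = 62)
  reads_path <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(g, coverage = 30, read_len = 150, seed = 63,
                 path = reads_path)
  reads <- stream_reads(reads_path)
  ks <- c(40L, 33L)
  filters <- stats::setNames(
    lapply(ks, function(k) build_cascading_filter(reads, k, optimal_bits(4e4, 0.005))),
    ks)
  asm <- data.frame(id = "draft", desc = "", seq = cor$draft$seq,
                    stringsAsFactors = FALSE)

  prefix <- file.path(withr::local_tempdir(), "sweep")
  swept <- ksweep_polish(asm, filters, ks, out_prefix = prefix)

  # replay: applying each iteration's changes to its input reproduces its
  # output up to soft-masking
  stage0 <- asm$seq
  stage1 <- polish_contig(stage0, filters[["40"]])$contig$seq
  tsv40 <- read.delim(paste0(prefix, ".k40_changes.tsv"),
                      colClasses = c(ref = "character", alt = "character"))
  tsv40$ref[is.na(tsv40$ref)] <- ""
  tsv40$alt[is.na(tsv40$alt)] <- ""
  expect_identical(toupper(apply_edits(stage0, tsv40)), toupper(stage1))

  # monotone mask: lowercase positions never shrink across iterations
  m1 <- lowercase_positions(stage1)
  m2 <- lowercase_positions(swept$assembly$seq)
  expect_true(all(m1 %in% m2))

  # a single-k sweep is polish_contig applied to every contig
  one <- ksweep_polish(asm, filters["40"], 40L)
  expect_identical(one$assembly$seq, stage1)
})

test_that("non-decreasing k values are a configuration error", {
  asm <- data.frame(id = "c", desc = "", seq = "ACGT",
                    stringsAsFactors = FALSE)
  expect_error(ksweep_polish(asm, list(), c(25L, 40L)),
               "k-mer lengths must be passed in decreasing order")
  bf <- bloom_filter(1e3, k = 40)
  expect_error(ksweep_polish(asm, list("40" = bf), c(40L, 33L)),
               "no Bloom filter supplied for k = 33")
})
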