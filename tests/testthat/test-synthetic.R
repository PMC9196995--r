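test_that("genome simulation is deterministic and uniform over ACGT", {
  g1 <- simulate_genome(5000, seed = 101)
  g2 <- simulate_genome(5000, seed = 101)
  g3 <- simulate_genome(5000, seed = 102)
  expect_identical(g1$seq, g2$seq)
  expect_false(identical(g1$seq, g3$seq))
  expect_identical(nchar(g1$seq), 5000L)
  expect_true(grepl("^[ACGT]+$", g1$seq))
  tab <- table(strsplit(g1$seq, "")[[1]])
  expect_true(all(tab > 5000 / 4 * 0.8))  # roughly uniform composition
})

test_that("corruption events are recorded faithfully against both coordinates", {
  g <- simulate_genome(50000, seed = 103)
  cor <- corrupt_genome(g, seed = 104)
  ev <- cor$truth$events
  expect_gt(nrow(ev), 0)
  # replaying the event log on the truth reproduces the draft
  expect_identical(replay_events(g$seq, ev), cor$draft$seq)
  # ref matches the truth at pos; alt matches the draft at draft_pos
  for (t in seq_len(nrow(ev))) {
    if (nchar(ev$ref[t]) > 0) {
      expect_identical(substr(g$seq, ev$pos[t],
                              ev$pos[t] + nchar(ev$ref[t]) - 1L), ev$ref[t])
    }
    if (nchar(ev$alt[t]) > 0) {
      expect_identical(substr(cor$draft$seq, ev$draft_pos[t],
                              ev$draft_pos[t] + nchar(ev$alt[t]) - 1L),
                       ev$alt[t])
    }
  }
})

test_that("N gaps are disjoint, full-length and well separated", {
  g <- simulate_genome(50000, seed = 105)
  cor <- corrupt_genome(g, seed = 106)
  gaps <- cor$truth$gap_intervals
  expect_identical(nrow(gaps), 3L)
  expect_true(all(nchar(gaps$ref) == 100))
  expect_true(all(gaps$alt == strrep("N", 100)))
  pos <- sort(gaps$pos)
  expect_true(all(diff(pos) >= 100 + 500))          # min_sep apart
  expect_true(all(pos > 500 & pos + 100 <= 50000 - 500))  # away from ends
})

test_that("interval placement fails loudly when the genome is too short", {
  g <- simulate_genome(1500, seed = 107)
  expect_error(corrupt_genome(g, seed = 108),
               "could not place disjoint intervals")
})

test_that("simulated reads match the requested coverage and length", {
  g <- simulate_genome(3000, seed = 109)
  path <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(g, coverage = 10, read_len = 100, seed = 110, path = path)
  reads <- stream_reads(path)
  expect_length(reads, round(10 * 3000 / 100))
  expect_true(all(nchar(reads) == 100))
  # error-free reads are exact substrings of the genome or its complement
  rc <- oracle_revcomp(g$seq)
  hits <- vapply(reads[1:50], function(r) {
    grepl(r, g$seq, fixed = TRUE) || grepl(r, rc, fixed = TRUE)
  }, logical(1))
  expect_true(all(hits))
})

test_that("read errors appear at the requested rate", {
  g <- simulate_genome(3000, seed = 111)
  path <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(g, coverage = 5, read_len = 100, error_rate = 0.05,
                 seed = 112, path = path)
  reads <- stream_reads(path)
  rc <- oracle_revcomp(g$seq)
  exact <- vapply(reads, function(r) {
    grepl(r, g$seq, fixed = TRUE) || grepl(r, rc, fixed = TRUE)
  }, logical(1))
  # at 5% per-base error almost no 100 nt read stays exact
  expect_lt(mean(exact), 0.05)
})

test_that("the evaluator is exact on hand-constructed assemblies", {
  g <- random_dna(10000, seed = 113)
  same <- evaluate_assembly(g, g)
  expect_equal(same$mismatches_per_100kbp, 0)
  expect_equal(same$indels_per_100kbp, 0)
  expect_equal(same$edit_distance, 0)
  expect_equal(same$alignment_columns, 10000)

  one_sub <- g
  substr(one_sub, 5000, 5000) <- if (substr(g, 5000, 5000) == "A") "C" else "A"
  m <- evaluate_assembly(one_sub, g)
  expect_equal(m$mismatch_columns, 1)
  expect_equal(m$mismatches_per_100kbp, 1e5 / 10000)
  expect_equal(m$gap_openings, 0)

  # one 3 nt deletion: a single gap event, three gap columns
  del <- paste0(substr(g, 1, 4999), substr(g, 5003, 10000))
  d <- evaluate_assembly(del, g)
  expect_equal(d$gap_openings, 1)
  expect_equal(d$indels_per_100kbp, 1e5 / d$alignment_columns)
  expect_equal(d$edit_distance, 3)

  # N and lowercase bookkeeping
  marked <- paste0(substr(g, 1, 100), "NNNNN", tolower(substr(g, 106, 115)),
                   substr(g, 116, 10000))
  b <- evaluate_assembly(marked, g)
  expect_equal(b$remaining_n, 5)
  expect_equal(b$remaining_lowercase, 10)
  expect_equal(b$mismatch_columns, 5)  # N columns count as mismatches
})

test_that("reversion scoring distinguishes draft, polished and truth", {
  g <- simulate_genome(30000, seed = 114)
  cor <- corrupt_genome(g, n_gaps = 1, seed = 115)
  expect_equal(score_reversion(g$seq, cor$truth), 1)
  expect_lt(score_reversion(cor$draft$seq, cor$truth), 0.25)
  clean <- corrupt_genome(g, sub_rate = 0, indel_rate = 0, n_gaps = 0,
                          seed = 116)
  expect_true(is.nan(score_reversion(g$seq, clean$truth)))
})

test_that("the standard fixture writes a parseable draft and read set", {
  dir <- withr::local_tempdir()
  fx <- synthetic_fixture(117, dir = dir, genome_len = 20000, coverage = 10)
  expect_true(file.exists(fx$draft_path))
  expect_true(file.exists(fx$reads_path))
  draft <- read_fasta(fx$draft_path)
  expect_identical(draft$seq, fx$draft$seq)
  expect_identical(nchar(fx$genome$seq), 20000L)
  reads <- stream_reads(fx$reads_path)
  expect_length(reads, round(10 * 20000 / 150))
  # regenerating with the same seed reproduces the files byte for byte
  dir2 <- withr::local_tempdir()
  fx2 <- synthetic_fixture(117, dir = dir2, genome_len = 20000, coverage = 10)
  expect_identical(unname(tools::md5sum(fx$draft_path)),
                   unname(tools::md5sum(fx2$draft_path)))
  expect_identical(unname(tools::md5sum(fx$reads_path)),
                   unname(tools::md5sum(fx2$reads_path)))
})
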