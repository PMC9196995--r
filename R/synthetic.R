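#' Simulate a random genome
#'
#' Uniform ACGT composition; deterministic for a fixed seed.
#'
#' @param length Genome length in nt (>= 1).
#' @param seed Integer seed.
#' @param id Record id (default "truth").
#' @return A record: list with `id`, `desc`, `seq`.
#' @export
simulate_genome <- function(length, seed, id = "truth") {
  stopifnot(length >= 1)
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
  list(id = id, desc = "", seq = seq)
}

#' Corrupt a genome into a draft assembly with recorded truth
#'
#' Injects the error classes a finishing pipeline must handle:
#' substitutions, small indels (1 to `max_indel` nt), disjoint N-gaps, and
#' optional scrambled stretches (random sequence of the same length,
#' emulating locally mis-assembled regions that only soft-masking plus gap
#' filling can repair). Every event is recorded so the draft can be
#' reconstructed and the polishing result scored against truth.
#'
#' @param genome A record (from [simulate_genome()]) or sequence string.
#' @param sub_rate Per-base substitution probability (default 0.002).
#' @param indel_rate Per-base indel event probability (default 2e-4).
#' @param max_indel Largest indel, nt (default 5; lengths uniform in
#'   1..max_indel, insertion or deletion with equal probability).
#' @param n_gaps Number of N-gaps (default 3).
#' @param gap_len Length of each N-gap (default 100).
#' @param n_scrambles Number of scrambled stretches (default 0).
#' @param scramble_len Length of each scrambled stretch (default 300).
#' @param seed Integer seed.
#' @param min_sep Minimum separation between placed intervals and from the
#'   sequence ends (default 500, keeping gap flanks clean).
#' @return List with `draft` (record) and `truth` (a `synthetic_truth`:
#'   `genome`, `events` data.frame with `pos` 1-based on the genome,
#'   `kind`, `ref`, `alt`, `draft_pos`; `mutations`, `gap_intervals`,
#'   `mask_intervals` views of it; and `seed`).
#' @export
corrupt_genome <- function(genome, sub_rate = 0.002, indel_rate = 2e-4,
                           max_indel = 5L, n_gaps = 3L, gap_len = 100L,
                           n_scrambles = 0L, scramble_len = 300L, seed,
                           min_sep = 500L) {
  if (is.character(genome)) genome <- list(id = "truth", desc = "",
                                           seq = genome)
  stopifnot(sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1)
  g <- genome$seq
  L <- nchar(g)
  set.seed(seed)

  ivals <- place_intervals(L, c(rep(gap_len, n_gaps),
                                rep(scramble_len, n_scrambles)), min_sep)
  kinds_iv <- c(rep("gap", n_gaps), rep("scramble", n_scrambles))

  in_interval <- function(p) {
    if (nrow(ivals) == 0) return(rep(FALSE, length(p)))
    out <- rep(FALSE, length(p))
    for (t in seq_len(nrow(ivals))) {
      out <- out | (p >= ivals$start[t] - max_indel &
                      p <= ivals$end[t] + max_indel)
    }
    out
  }

  bases <- c("A", "C", "G", "T")
  sub_pos <- which(runif(L) < sub_rate)
  sub_pos <- sub_pos[!in_interval(sub_pos)]
  indel_pos <- which(runif(L) < indel_rate)
  indel_pos <- indel_pos[!in_interval(indel_pos)]
  # keep point events isolated from each other
  all_pos <- sort(c(sub_pos, indel_pos))
  crowded <- all_pos[c(FALSE, diff(all_pos) <= 2 * max_indel)]
  sub_pos <- setdiff(sub_pos, crowded)
  indel_pos <- setdiff(indel_pos, crowded)

  events <- list()
  for (p in sub_pos) {
    ref <- substr(g, p, p)
    alt <- sample(setdiff(bases, ref), 1L)
    events[[length(events) + 1L]] <-
      data.frame(pos = p, kind = "substitution", ref = ref, alt = alt,
                 stringsAsFactors = FALSE)
  }
  for (p in indel_pos) {
    len <- sample.int(max_indel, 1L)
    if (runif(1) < 0.5) {  # extra bases present in the draft
      alt <- paste(sample(bases, len, replace = TRUE), collapse = "")
      events[[length(events) + 1L]] <-
        data.frame(pos = p, kind = "insertion", ref = "", alt = alt,
                   stringsAsFactors = FALSE)
    } else {               # bases missing from the draft
      if (p + len - 1L > L) next
      ref <- substr(g, p, p + len - 1L)
      events[[length(events) + 1L]] <-
        data.frame(pos = p, kind = "deletion", ref = ref, alt = "",
                   stringsAsFactors = FALSE)
    }
  }
  if (nrow(ivals) > 0) {
    for (t in seq_len(nrow(ivals))) {
      s <- ivals$start[t]; e <- ivals$end[t]
      ref <- substr(g, s, e)
      alt <- if (kinds_iv[t] == "gap") strrep("N", e - s + 1L) else
        paste(sample(bases, e - s + 1L, replace = TRUE), collapse = "")
      events[[length(events) + 1L]] <-
        data.frame(pos = s, kind = kinds_iv[t], ref = ref, alt = alt,
                   stringsAsFactors = FALSE)
    }
  }
  events <- if (length(events) > 0) do.call(rbind, events) else
    data.frame(pos = numeric(), kind = character(), ref = character(),
               alt = character(), stringsAsFactors = FALSE)
  events <- events[order(events$pos), , drop = FALSE]
  row.names(events) <- NULL

  # draft positions: cumulative shift from preceding events
  shift <- cumsum(c(0, nchar(events$alt) - nchar(events$ref)))
  events$draft_pos <- events$pos + utils::head(shift, -1)

  draft_seq <- replay_events(g, events)
  truth <- structure(
    list(genome = genome, events = events,
         mutations = events[events$kind %in%
                              c("substitution", "insertion", "deletion"), ,
                            drop = FALSE],
         gap_intervals = events[events$kind == "gap", , drop = FALSE],
         mask_intervals = events[events$kind == "scramble", , drop = FALSE],
         seed = seed),
    class = "synthetic_truth")
  draft <- list(id = "draft", desc = "synthetic draft", seq = draft_seq)
  list(draft = draft, truth = truth)
}

place_intervals <- function(L, lens, min_sep, max_tries = 1000L) {
  placed <- data.frame(start = integer(), end = integer())
  for (len in lens) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      s <- sample.int(L - len - 2L * min_sep, 1L) + min_sep
      e <- s + len - 1L
      if (nrow(placed) == 0 ||
          all(e < placed$start - min_sep | s > placed$end + min_sep)) {
        placed <- rbind(placed, data.frame(start = s, end = e))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place disjoint intervals; genome too short",
                  call. = FALSE)
  }
  placed
}

#' Reconstruct the draft from recorded corruption events
#'
#' @param genome_seq The truth genome sequence.
#' @param events The `events` table of a `synthetic_truth`.
#' @return The draft sequence.
#' @export
replay_events <- function(genome_seq, events) {
  if (nrow(events) == 0) return(genome_seq)
  ord <- order(events$pos, decreasing = TRUE)
  for (t in ord) {
    p <- events$pos[t]
    seq_len_ <- nchar(genome_seq)
    genome_seq <- paste0(substr(genome_seq, 1L, p - 1L), events$alt[t],
                         substr(genome_seq, p + nchar(events$ref[t]),
                                seq_len_))
  }
  genome_seq
}

#' Simulate error-bearing short reads and write them as FASTQ
#'
#' Reads are drawn uniformly from both strands to the target mean coverage
#' (`round(coverage * L / read_len)` reads), with independent per-base
#' substitution errors and constant dummy qualities. Deterministic for a
#' fixed seed.
#'
#' @param genome A record or sequence string.
#' @param coverage Mean coverage (default 30).
#' @param read_len Read length, nt (default 150; must not exceed the
#'   genome).
#' @param error_rate Per-base substitution error rate (default 0).
#' @param seed Integer seed.
#' @param path Output FASTQ path; gzip-compressed when it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
simulate_reads <- function(genome, coverage = 30, read_len = 150L,
                           error_rate = 0, seed, path) {
  if (is.list(genome)) genome <- genome$seq
  L <- nchar(genome)
  stopifnot(read_len <= L)
  set.seed(seed)
  n_reads <- round(coverage * L / read_len)
  starts <- sample.int(L - read_len + 1L, n_reads, replace = TRUE)
  minus <- runif(n_reads) < 0.5
  seqs <- substring(genome, starts, starts + read_len - 1L)
  if (any(minus)) {
    seqs[minus] <- vapply(seqs[minus], cpp_revcomp, "", USE.NAMES = FALSE)
  }
  if (error_rate > 0) {
    bases <- c("A", "C", "G", "T")
    for (r in seq_len(n_reads)) {
      hits <- which(runif(read_len) < error_rate)
      for (p in hits) {
        old <- substr(seqs[r], p, p)
        substr(seqs[r], p, p) <- sample(setdiff(bases, old), 1L)
      }
    }
  }
  qual <- strrep("I", read_len)
  lines <- character(4L * n_reads)
  lines[seq(1L, by = 4L, length.out = n_reads)] <-
    paste0("@read", seq_len(n_reads))
  lines[seq(2L, by = 4L, length.out = n_reads)] <- seqs
  lines[seq(3L, by = 4L, length.out = n_reads)] <- "+"
  lines[seq(4L, by = 4L, length.out = n_reads)] <- qual
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  writeLines(lines, con)
  close(con)
  invisible(path)
}

#' Score a polished assembly against the truth genome
#'
#' Banded global alignment with unit mismatch and gap costs between the
#' polished sequence and the truth genome (both uppercased; `N` columns
#' count as mismatches). Indels are counted per event (gap opening), not
#' per base, mirroring the per-100-kbp style of assembly QC reports. The
#' band is widened automatically until the optimal path stays clear of the
#' band edge, so the alignment is exact.
#'
#' @param polished A record or sequence string (one contig).
#' @param truth_genome The truth record or sequence string.
#' @return List with `mismatches_per_100kbp`, `indels_per_100kbp`,
#'   `remaining_n`, `remaining_lowercase`, `alignment_columns`,
#'   `mismatch_columns`, `gap_openings`, `edit_distance`.
#' @export
evaluate_assembly <- function(polished, truth_genome) {
  if (is.list(polished)) polished <- polished$seq
  if (is.list(truth_genome)) truth_genome <- truth_genome$seq
  remaining_n <- nchar(gsub("[^Nn]", "", polished))
  remaining_lower <- nchar(gsub("[^a-z]", "", polished))
  a <- toupper(truth_genome)
  b <- toupper(polished)
  extra <- max(64L, 32L + abs(nchar(a) - nchar(b)))
  repeat {
    al <- cpp_banded_align(a, b, extra)
    if (!al$hit_boundary || extra >= max(nchar(a), nchar(b))) break
    extra <- extra * 2L
  }
  list(mismatches_per_100kbp = 1e5 * al$mismatches / al$columns,
       indels_per_100kbp = 1e5 * al$gap_openings / al$columns,
       remaining_n = remaining_n,
       remaining_lowercase = remaining_lower,
       alignment_columns = al$columns,
       mismatch_columns = al$mismatches,
       gap_openings = al$gap_openings,
       edit_distance = al$distance)
}

#' Write evaluation metrics as a small TSV
#'
#' @param metrics List from [evaluate_assembly()] (or several, named).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  if (!is.null(metrics$mismatches_per_100kbp)) metrics <- list(metrics)
  rows <- do.call(rbind, lapply(metrics, as.data.frame))
  rows <- cbind(assembly = names(metrics) %||% seq_along(metrics), rows)
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fraction of injected errors reverted in a polished assembly
#'
#' An injected mutation counts as reverted when the truth genome's local
#' context around it (`flank` nt each side) occurs verbatim in the polished
#' sequence — on a random genome the context is effectively unique.
#'
#' @param polished A record or sequence string.
#' @param truth A `synthetic_truth`.
#' @param flank Context width, nt (default 25).
#' @return Fraction in `[0, 1]` (`NaN` when no mutations were injected).
#' @export
score_reversion <- function(polished, truth, flank = 25L) {
  if (is.list(polished)) polished <- polished$seq
  polished <- toupper(polished)
  g <- truth$genome$seq
  ev <- truth$mutations
  if (nrow(ev) == 0) return(NaN)
  hit <- vapply(seq_len(nrow(ev)), function(t) {
    lo <- max(1L, ev$pos[t] - flank)
    hi <- min(nchar(g), ev$pos[t] + nchar(ev$ref[t]) + flank - 1L)
    grepl(substr(g, lo, hi), polished, fixed = TRUE)
  }, logical(1))
  mean(hit)
}

#' The package's default synthetic benchmark fixture
#'
#' A 100 kb uniform random genome; a draft carrying 0.2% substitutions,
#' 0.02% indels of 1-5 nt and three disjoint 100 nt N-gaps; and error-free
#' 150 bp reads at 30x coverage. Files are written under `dir`.
#'
#' @param seed Integer master seed (sub-seeds are derived from it).
#' @param dir Output directory (created if needed).
#' @param genome_len Genome length (default 1e5).
#' @param coverage Read coverage (default 30).
#' @return List with `genome`, `draft`, `truth`, `draft_path`,
#'   `reads_path`, `dir`.
#' @export
synthetic_fixture <- function(seed, dir = tempfile("fixture"),
                              genome_len = 1e5, coverage = 30) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(genome_len, seed = seed)
  cor <- corrupt_genome(genome, seed = seed + 1L)
  draft_path <- file.path(dir, "draft.fa")
  write_fasta(data.frame(id = cor$draft$id, desc = cor$draft$desc,
                         seq = cor$draft$seq, stringsAsFactors = FALSE),
              draft_path)
  reads_path <- file.path(dir, "reads.fastq")
  simulate_reads(genome, coverage = coverage, read_len = 150L,
                 error_rate = 0, seed = seed + 2L, path = reads_path)
  list(genome = genome, draft = cor$draft, truth = cor$truth,
       draft_path = draft_path, reads_path = reads_path, dir = dir)
}
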