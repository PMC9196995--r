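#' Configuration for a finishing run
#'
#' Validates everything before any compute: k values must be strictly
#' decreasing, input files readable and the Bloom size parseable.
#'
#' @param seqs Path to the draft assembly FASTA.
#' @param reads Character vector of FASTQ paths (plain or `.gz`).
#' @param ks Strictly decreasing k values (e.g. `c(80, 65, 50)`).
#' @param b Gap-filler Bloom size in bytes with optional K/M/G suffix
#'   (e.g. `"200M"`), or `"auto"` to size from the read k-mer spectra.
#' @param f_target Target false positive rate for auto-sizing (default
#'   0.005).
#' @param h Hash functions per filter (default 1).
#' @param polish A [polish_config()].
#' @param gapfill A [gapfill_config()].
#' @param seed Integer seed for every stochastic component, including the
#'   Bloom hash family (default 13).
#' @param outdir Output directory (created if needed).
#' @return A `finish_config` list.
#' @export
finish_config <- function(seqs, reads, ks, b = "auto", f_target = 0.005,
                          h = 1L, polish = polish_config(),
                          gapfill = gapfill_config(), seed = 13L,
                          outdir = ".") {
  ks <- assert_decreasing_ks(ks)
  if (!file.exists(seqs)) stop("draft assembly not found: ", seqs,
                               call. = FALSE)
  for (p in reads) {
    if (!file.exists(p)) stop("reads file not found: ", p, call. = FALSE)
  }
  if (!identical(b, "auto")) parse_bloom_size(b)  # errors if unparseable
  stopifnot(f_target > 0, f_target < 1)
  structure(list(seqs = seqs, reads = reads, ks = ks, b = b,
                 f_target = f_target, h = as.integer(h), polish = polish,
                 gapfill = gapfill, seed = as.integer(seed),
                 outdir = outdir),
            class = "finish_config")
}

#' Run the full finishing pipeline
#'
#' Four stages behind one call: (1) build one multiplicity-filtered
#' cascading Bloom filter per k from the short reads; (2) iterative
#' long-to-short k-sweep polishing of the draft, writing per-k change
#' tables; (3) consolidation of short unmasked islands between soft-masked
#' runs; (4) k-sweep gap filling of N-gaps and soft-masked regions through
#' the implicit de Bruijn graph. One filter per k is built once and shared
#' by the polishing and gap-filling stages. Each stage's output is written
#' before the next begins, and the run halts at the first failure.
#'
#' @param cfg A [finish_config()].
#' @return (Invisibly) a named list of output paths — `edited`
#'   (`.ntedit_edited.fa`), `changes` (per-k `_changes.tsv`), `prepd`
#'   (`.prepd.fa`), `final` (`.sealer_scaffold.fa`), `sealer_log`, plus
#'   `stats` (edit and gap-closure counts).
#' @export
run_finish <- function(cfg) {
  stopifnot(inherits(cfg, "finish_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stem <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
              basename(cfg$seqs), ignore.case = TRUE)
  out <- function(suffix) file.path(cfg$outdir, paste0(stem, suffix))

  assembly <- read_fasta(cfg$seqs)
  reads <- stream_reads(cfg$reads)

  # stage 1: filters (sized by b, or from the k-mer spectra at f_target)
  if (identical(cfg$b, "auto")) {
    spectra <- lapply(cfg$ks, function(k) kmer_spectrum(reads, k))
    spec <- auto_size(spectra, f = cfg$f_target, h = cfg$h)
    if (spec$n == 0) {
      stop("reads contain no repeated k-mers at the requested k values; ",
           "cannot size a Bloom filter", call. = FALSE)
    }
    m <- spec$m
  } else {
    m <- parse_bloom_size(cfg$b)
  }
  filters <- lapply(cfg$ks, function(k) {
    build_cascading_filter(reads, k, m, h = cfg$h, seed = cfg$seed)
  })
  names(filters) <- as.character(cfg$ks)

  write_run_header(cfg, m, stem)

  # stage 2: iterative polishing
  pol <- ksweep_polish(assembly, filters, cfg$ks, cfg$polish,
                       out_prefix = file.path(cfg$outdir, stem))
  edited_path <- out(".ntedit_edited.fa")
  write_fasta(pol$assembly, edited_path)

  # stage 3: consolidate short unmasked islands
  prepd <- pol$assembly
  prepd$seq <- vapply(prepd$seq, consolidate_mask, "",
                      k_min = min(cfg$ks), USE.NAMES = FALSE)
  prepd_path <- out(".ntedit_edited.prepd.fa")
  write_fasta(prepd, prepd_path)

  # stage 4: gap filling
  log_path <- out(".sealer_log.txt")
  fill <- ksweep_fill(prepd, filters, cfg$ks, cfg$gapfill,
                      include_soft = TRUE, log_path = log_path)
  final_path <- out(".ntedit_edited.prepd.sealer_scaffold.fa")
  write_fasta(fill$assembly, final_path)

  message("ntEdit and Sealer polishing steps complete! ",
          "Polished assembly can be found in: ", final_path)
  invisible(list(
    edited = edited_path,
    changes = file.path(cfg$outdir,
                        paste0(stem, ".k", cfg$ks, "_changes.tsv")),
    prepd = prepd_path,
    final = final_path,
    sealer_log = log_path,
    stats = list(n_edits = sum(vapply(pol$changes, nrow, integer(1))),
                 gaps_closed = fill$closed_per_k)
  ))
}

write_run_header <- function(cfg, m, stem) {
  lines <- c(
    "# finishing run configuration",
    paste0("seqs=", cfg$seqs),
    paste0("reads=", paste(cfg$reads, collapse = ",")),
    paste0("ks=", paste(cfg$ks, collapse = ",")),
    paste0("b=", cfg$b),
    paste0("bloom_bits=", format(m, scientific = FALSE)),
    paste0("f_target=", cfg$f_target),
    paste0("h=", cfg$h),
    paste0("seed=", cfg$seed),
    paste0("trigger_frac=", cfg$polish$trigger_frac),
    paste0("accept_frac=", cfg$polish$accept_frac),
    paste0("max_indel=", cfg$polish$max_indel),
    paste0("flank_len=", cfg$gapfill$flank_len),
    paste0("slack=", cfg$gapfill$slack),
    paste0("max_branches=", format(cfg$gapfill$max_branches,
                                   scientific = FALSE)),
    paste0("max_paths=", cfg$gapfill$max_paths)
  )
  writeLines(lines, file.path(cfg$outdir, paste0(stem, ".run_info.txt")))
}

#' Bloom filter sizing report for a read set
#'
#' Computes the exact k-mer spectrum of the reads at each k, writes the
#' per-k histogram files (`freq_k<k>.hist`), derives the repeated-k-mer
#' count `n = F0 - f1` per k, and sizes the filter from the largest `n` at
#' the target false positive rate.
#'
#' @param reads Character vector of FASTQ paths.
#' @param ks k values planned for the sweep.
#' @param f_target Target false positive rate (default 0.005).
#' @param outdir Directory for histogram files (default `"."`); `NULL`
#'   skips writing them.
#' @return List with `per_k` (data.frame: `k`, `F0`, `F1`, `f1`, `n`),
#'   `n`, `m` (bits), `mb`, `f_target`.
#' @export
run_bloom_size <- function(reads, ks, f_target = 0.005, outdir = ".") {
  seqs <- stream_reads(reads)
  spectra <- lapply(ks, function(k) kmer_spectrum(seqs, k))
  if (all(vapply(spectra, function(s) s$F1, numeric(1)) == 0)) {
    stop("no k-mers extracted from the reads at any requested k; ",
         "are the reads shorter than k?", call. = FALSE)
  }
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (s in spectra) write_hist(s, outdir)
  }
  per_k <- data.frame(
    k = as.integer(ks),
    F0 = vapply(spectra, function(s) s$F0, numeric(1)),
    F1 = vapply(spectra, function(s) s$F1, numeric(1)),
    f1 = vapply(spectra, function(s) s$f1, numeric(1))
  )
  per_k$n <- per_k$F0 - per_k$f1
  spec <- auto_size(spectra, f = f_target)
  list(per_k = per_k, n = spec$n, m = spec$m, mb = spec$mb,
       f_target = f_target)
}
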