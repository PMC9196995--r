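#' Gap-filling limits
#'
#' @param flank_len Clean flank length extracted on each side of a gap, in
#'   nt (default 100).
#' @param slack Extra path length allowed beyond the gap length, per side
#'   (default 100 nt; the traversal abandons paths longer than
#'   `gap length + 2 * slack`).
#' @param max_branches Node-expansion budget per gap before the search
#'   aborts (default 10000).
#' @param max_paths Successful paths collected before stopping (default 2;
#'   a gap is only accepted when all collected paths agree).
#' @return A `gapfill_config` list.
#' @export
gapfill_config <- function(flank_len = 100L, slack = 100L,
                           max_branches = 10000, max_paths = 2L) {
  stopifnot(flank_len >= 1, slack >= 0, max_branches >= 1, max_paths >= 1)
  structure(list(flank_len = as.integer(flank_len), slack = as.integer(slack),
                 max_branches = as.numeric(max_branches),
                 max_paths = as.integer(max_paths)),
            class = "gapfill_config")
}

#' Detect gaps in a contig
#'
#' Maximal `N` runs are always gaps; with `include_soft`, maximal lowercase
#' (soft-masked) runs are too. Adjacent hard and soft runs merge into one
#' gap, recorded as hard for bookkeeping.
#'
#' @param contig A record (list with `id`, `seq`) or a sequence string.
#' @param include_soft Treat soft-masked runs as gaps (the polishing
#'   pipeline's hand-off channel; off by default, mirroring gap fillers
#'   that only see `N`s unless told otherwise).
#' @return data.frame with `contig_id`, `start`, `end` (0-based half-open),
#'   `kind`, `original` (the characters currently in the interval), sorted
#'   by start.
#' @export
detect_gaps <- function(contig, include_soft = FALSE) {
  if (is.character(contig)) contig <- list(id = "contig", seq = contig)
  runs <- find_runs(contig$seq)
  if (!include_soft) runs <- runs[runs$kind == "hard", , drop = FALSE]
  if (nrow(runs) == 0) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), kind = character(),
                      original = character(), stringsAsFactors = FALSE))
  }
  runs <- runs[order(runs$start), , drop = FALSE]
  # merge touching runs; hard wins
  merged <- runs[1, , drop = FALSE]
  for (t in seq_len(nrow(runs))[-1]) {
    last <- nrow(merged)
    if (runs$start[t] == merged$end[last]) {
      merged$end[last] <- runs$end[t]
      if (runs$kind[t] == "hard") merged$kind[last] <- "hard"
    } else {
      merged <- rbind(merged, runs[t, , drop = FALSE])
    }
  }
  data.frame(contig_id = contig$id %||% "contig",
             start = merged$start, end = merged$end, kind = merged$kind,
             original = substring(contig$seq, merged$start + 1L, merged$end),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Traverse the implicit de Bruijn graph between two flanks
#'
#' Depth-first extension from the terminal k-mer of the left flank through
#' the k-mer set held in the Bloom filter, until the initial k-mer of the
#' right flank is reached. Returns the bases spliced between the flanks for
#' each successful path (possibly empty when the flanks nearly overlap).
#'
#' @param bf The read `bloom_filter` (defines k and the k-mer set).
#' @param left_flank,right_flank Flanking sequences, each at least k long.
#' @param max_len Longest spliced sequence considered, in nt.
#' @param max_branches Node-expansion budget.
#' @param max_paths Stop after this many successful paths.
#' @return List with `paths` (character vector), `n_expanded`, `aborted`
#'   (branch budget hit) and `hit_max_paths`.
#' @export
traverse_gap <- function(bf, left_flank, right_flank, max_len,
                         max_branches = 10000, max_paths = 2L) {
  stopifnot(inherits(bf, "bloom_filter"))
  cpp_traverse(bf$ptr, left_flank, right_flank, as.numeric(max_len),
               as.numeric(max_branches), as.integer(max_paths))
}

#' Attempt to fill one gap
#'
#' Extracts clean (uppercase ACGT) flanks of up to `flank_len` nt adjacent
#' to the gap, truncating at contig ends or neighboring gaps, and runs the
#' de Bruijn traversal with `max_len = gap length + 2 * slack`. The fill is
#' accepted only when a single path is found, or when every collected path
#' is identical; the replacement is uppercase.
#'
#' @param seq The contig sequence.
#' @param gap One row of [detect_gaps()] output (list or data.frame row
#'   with `start`, `end`, `kind`).
#' @param bf The read `bloom_filter` for the current k.
#' @param cfg A [gapfill_config()].
#' @return List with `gap`, `status` ("filled"/"unfilled"), `k_used`,
#'   `fill` (or `NA`), `paths_found`, `reason` (`NA` when filled; otherwise
#'   "no-path", "too-many-paths" or "flank-too-short").
#' @export
fill_gap <- function(seq, gap, bf, cfg = gapfill_config()) {
  stopifnot(inherits(bf, "bloom_filter"))
  k <- bf$k
  left <- clean_flank(seq, gap$start, cfg$flank_len, backwards = TRUE)
  right <- clean_flank(seq, gap$end, cfg$flank_len, backwards = FALSE)
  unfilled <- function(reason, paths_found = 0L) {
    list(gap = gap, status = "unfilled", k_used = NA_integer_,
         fill = NA_character_, paths_found = paths_found, reason = reason)
  }
  if (nchar(left) < k || nchar(right) < k) {
    return(unfilled("flank-too-short"))
  }
  max_len <- (gap$end - gap$start) + 2L * cfg$slack
  tr <- traverse_gap(bf, left, right, max_len, cfg$max_branches,
                     cfg$max_paths)
  npaths <- length(tr$paths)
  if (npaths == 0) return(unfilled("no-path"))
  if (npaths > 1 && length(unique(tr$paths)) > 1) {
    return(unfilled("too-many-paths", npaths))
  }
  list(gap = gap, status = "filled", k_used = k,
       fill = toupper(tr$paths[[1]]), paths_found = npaths, reason = NA_character_)
}

# longest uppercase-ACGT stretch adjacent to position `pos` (0-based
# boundary), scanning backwards (left flank) or forwards (right flank)
clean_flank <- function(seq, pos, flank_len, backwards) {
  n <- nchar(seq)
  if (backwards) {
    lo <- max(0L, pos - flank_len)
    chunk <- substring(seq, lo + 1L, pos)
    m <- regmatches(chunk, regexpr("[ACGT]+$", chunk))
  } else {
    hi <- min(n, pos + flank_len)
    chunk <- substring(seq, pos + 1L, hi)
    m <- regmatches(chunk, regexpr("^[ACGT]+", chunk))
  }
  if (length(m) == 0) "" else m
}

#' Iterative long-to-short k-sweep gap filling
#'
#' For each k in decreasing order, detects the currently open gaps (hard
#' N-runs plus soft-masked regions) and attempts to fill each; accepted
#' fills are spliced in before the next k, and coordinates are re-derived
#' after every splice. After the sweep, unfilled soft-masked regions are
#' restored to uppercase (their best-effort sequence is retained) while
#' unfilled hard gaps remain `N`.
#'
#' @param assembly data.frame of records as from [read_fasta()].
#' @param filters Named list of `bloom_filter`s, one per k.
#' @param ks Strictly decreasing integer vector of k values. Values below
#'   40 trigger a warning: shorter k-mers make the traversal explode.
#' @param cfg A [gapfill_config()].
#' @param include_soft Also fill soft-masked regions (default TRUE; this is
#'   the pipeline's hand-off from the polisher).
#' @param log_path If non-NULL, the run log is written there.
#' @return List with `assembly` (final records, uppercase outside remaining
#'   N gaps), `log` (character vector: per-k
#'   `k=<k> gaps_closed=<n> gaps_remaining=<m>` lines plus one line per gap
#'   attempt) and `closed_per_k` (named integer vector).
#' @export
ksweep_fill <- function(assembly, filters, ks, cfg = gapfill_config(),
                        include_soft = TRUE, log_path = NULL) {
  ks <- assert_decreasing_ks(ks)
  missing_k <- setdiff(as.character(ks), names(filters))
  if (length(missing_k) > 0) {
    stop("no Bloom filter supplied for k = ",
         paste(missing_k, collapse = ", "), call. = FALSE)
  }
  if (min(ks) < 40) {
    warning("k below 40 is the practical lower limit for gap filling; ",
            "runtime may increase sharply", call. = FALSE)
  }
  log <- c(sprintf("gap filling: ks=%s flank_len=%d slack=%d max_branches=%g max_paths=%d",
                   paste(ks, collapse = ","), cfg$flank_len, cfg$slack,
                   cfg$max_branches, cfg$max_paths))
  closed_per_k <- setNames(integer(length(ks)), as.character(ks))
  for (k in ks) {
    bf <- filters[[as.character(k)]]
    closed <- 0L
    remaining <- 0L
    for (r in seq_len(nrow(assembly))) {
      contig <- list(id = assembly$id[r], seq = assembly$seq[r])
      gaps <- detect_gaps(contig, include_soft = include_soft)
      if (nrow(gaps) == 0) next
      # right-to-left so earlier intervals stay valid after splicing
      for (g in rev(seq_len(nrow(gaps)))) {
        gap <- as.list(gaps[g, , drop = FALSE])
        res <- fill_gap(contig$seq, gap, bf, cfg)
        if (res$status == "filled") {
          contig$seq <- paste0(substr(contig$seq, 1L, gap$start),
                               res$fill,
                               substr(contig$seq, gap$end + 1L,
                                      nchar(contig$seq)))
          closed <- closed + 1L
        } else {
          remaining <- remaining + 1L
        }
        log <- c(log, sprintf(
          "k=%d contig=%s interval=[%d,%d) kind=%s status=%s%s", k,
          gap$contig_id, gap$start, gap$end, gap$kind, res$status,
          if (res$status == "unfilled") paste0(" reason=", res$reason) else ""))
      }
      assembly$seq[r] <- contig$seq
    }
    closed_per_k[as.character(k)] <- closed
    log <- c(log, sprintf("k=%d gaps_closed=%d gaps_remaining=%d", k,
                          closed, remaining))
  }
  assembly$seq <- toupper(assembly$seq)
  if (!is.null(log_path)) writeLines(log, log_path)
  list(assembly = assembly, log = log, closed_per_k = closed_per_k)
}
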