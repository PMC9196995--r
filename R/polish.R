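#' Polishing thresholds
#'
#' @param trigger_frac Minimum fraction of a base's covering k-mers that
#'   must be absent from the read filter before the base is treated as
#'   suspect (default 0.5).
#' @param accept_frac Minimum fraction of covering k-mers a candidate edit
#'   must recover before it is applied (default 0.5).
#' @param max_indel Largest insertion/deletion considered, in nt (default 5).
#' @return A `polish_config` list.
#' @export
polish_config <- function(trigger_frac = 0.5, accept_frac = 0.5,
                          max_indel = 5L) {
  stopifnot(trigger_frac >= 0, trigger_frac <= 1,
            accept_frac >= 0, accept_frac <= 1, max_indel >= 0)
  structure(list(trigger_frac = trigger_frac, accept_frac = accept_frac,
                 max_indel = as.integer(max_indel)),
            class = "polish_config")
}

#' Enumerate candidate edits at a position
#'
#' Candidates at a suspect base are the 3 substitutions, every ACGT
#' insertion of 1 to `max_indel` nt before the base, and deletions of 1 to
#' `max_indel` bases starting at it (clipped at the contig end). The order
#' is fixed — substitutions, then insertions by length then lexicographic,
#' then deletions by length — and doubles as the tie-break, so the most
#' parsimonious edit wins among equally supported candidates.
#'
#' @param seq Contig sequence.
#' @param i 0-based position.
#' @param max_indel Largest indel length (default 5; 1372 candidates at an
#'   interior position).
#' @return data.frame with columns `kind`, `ref`, `alt`.
#' @export
enumerate_edits <- function(seq, i, max_indel = 5L) {
  cpp_enumerate_edits(seq, as.numeric(i), as.integer(max_indel))
}

#' Support of a candidate edit
#'
#' Applies the candidate to a local window and returns the fraction of
#' k-mers covering the edited locus that are present in the read filter.
#' Windows truncated at contig ends (or containing non-ACGT characters)
#' shrink the denominator; the ratio is always in `[0, 1]`.
#'
#' @param seq Contig sequence.
#' @param i 0-based position of the edit.
#' @param ref Replaced bases (`""` for an insertion).
#' @param alt Replacement bases (`""` for a deletion).
#' @param bf The read `bloom_filter` (its `k` is used).
#' @return Support fraction.
#' @export
edit_support <- function(seq, i, ref, alt, bf) {
  stopifnot(inherits(bf, "bloom_filter"))
  cpp_edit_support(seq, as.numeric(i), ref, alt, bf$ptr)
}

#' Polish one contig at a single k
#'
#' Left-to-right scan of the contig k-mers against the read filter. A base
#' is suspect when the k-mer ending at it is absent and at least
#' `trigger_frac` of all k-mers covering it are absent. At a suspect base
#' the best-supported candidate edit with support >= `accept_frac` is
#' applied (ties break by enumeration order) and the scan resumes at the
#' first k-mer past the edited locus; when no candidate qualifies the base
#' is soft-masked (lowercased). Existing `N` and lowercase characters are
#' never edited.
#'
#' @param contig A record (list or one-row data.frame with `id` and `seq`)
#'   or a plain sequence string.
#' @param bf Read `bloom_filter` built at the scanning k.
#' @param cfg A [polish_config()].
#' @return List with `contig` (edited record), `edits` (data.frame:
#'   `contig_id`, `position` 1-based on the pre-edit contig, `kind`, `ref`,
#'   `alt`, `support`, `k`) and `masked_bases` (newly lowercased count).
#'   A contig shorter than k is returned unchanged.
#' @export
polish_contig <- function(contig, bf, cfg = polish_config()) {
  stopifnot(inherits(bf, "bloom_filter"))
  if (is.character(contig)) contig <- list(id = "contig", desc = "",
                                           seq = contig)
  res <- cpp_polish_contig(contig$seq, bf$ptr, cfg$trigger_frac,
                           cfg$accept_frac, cfg$max_indel)
  edits <- res$edits
  edits <- data.frame(contig_id = rep(contig$id, nrow(edits)),
                      edits, k = rep(bf$k, nrow(edits)),
                      stringsAsFactors = FALSE)
  out <- contig
  out$seq <- res$seq
  list(contig = out, edits = edits, masked_bases = res$masked_bases)
}

#' Iterative long-to-short k-sweep polishing
#'
#' Runs [polish_contig()] over the whole assembly once per k, feeding each
#' iteration's output to the next. Larger k-mers disambiguate repeats;
#' shorter ones recover regions of low effective coverage, so the sweep
#' must go from long to short. Soft-masked positions accumulate across
#' iterations.
#'
#' @param assembly data.frame of records as from [read_fasta()].
#' @param filters Named list of `bloom_filter`s, one per k (names are the k
#'   values).
#' @param ks Strictly decreasing integer vector of k values.
#' @param cfg A [polish_config()].
#' @param out_prefix If non-NULL, per-k changes are written to
#'   `<out_prefix>.k<k>_changes.tsv`.
#' @return List with `assembly` (polished records) and `changes` (named
#'   list of per-k edit data.frames, in sweep order).
#' @export
ksweep_polish <- function(assembly, filters, ks, cfg = polish_config(),
                          out_prefix = NULL) {
  ks <- assert_decreasing_ks(ks)
  missing_k <- setdiff(as.character(ks), names(filters))
  if (length(missing_k) > 0) {
    stop("no Bloom filter supplied for k = ",
         paste(missing_k, collapse = ", "), call. = FALSE)
  }
  changes <- list()
  for (k in ks) {
    bf <- filters[[as.character(k)]]
    per_k <- vector("list", nrow(assembly))
    for (r in seq_len(nrow(assembly))) {
      res <- polish_contig(as.list(assembly[r, , drop = FALSE]), bf, cfg)
      assembly$seq[r] <- res$contig$seq
      per_k[[r]] <- res$edits
    }
    edits_k <- if (nrow(assembly) > 0) do.call(rbind, per_k) else
      empty_edits()
    changes[[as.character(k)]] <- edits_k
    if (!is.null(out_prefix) && nrow(assembly) > 0) {
      write.table(edits_k,
                  paste0(out_prefix, ".k", k, "_changes.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(assembly = assembly, changes = changes)
}

empty_edits <- function() {
  data.frame(contig_id = character(), position = numeric(),
             kind = character(), ref = character(), alt = character(),
             support = numeric(), k = integer(), stringsAsFactors = FALSE)
}

#' Replay recorded edits onto a sequence
#'
#' Edit positions are 1-based on the pre-edit sequence of one polishing
#' iteration, so they can be applied in decreasing position order without
#' interference. Replaying an iteration's change table onto its input
#' reproduces its output (uppercase comparison; soft-masking aside).
#'
#' @param seq The pre-edit sequence of one iteration.
#' @param edits data.frame with `position`, `kind`, `ref`, `alt`.
#' @return The edited sequence.
#' @export
apply_edits <- function(seq, edits) {
  if (nrow(edits) == 0) return(seq)
  ord <- order(edits$position, decreasing = TRUE)
  for (t in ord) {
    p <- edits$position[t]
    ref <- edits$ref[t]
    alt <- edits$alt[t]
    left <- substr(seq, 1L, p - 1L)
    right <- substr(seq, p + nchar(ref), nchar(seq))
    seq <- paste0(left, alt, right)
  }
  seq
}
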