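#' Find soft-masked and hard-gap runs in a sequence
#'
#' Maximal lowercase runs are soft masks; maximal `N`/`n` runs are hard
#' gaps (`N` beats case, so an `n` is hard). Intervals are 0-based
#' half-open, sorted by start.
#'
#' @param seq A sequence string.
#' @return data.frame with columns `start`, `end`, `kind` ("soft"/"hard").
#' @export
find_runs <- function(seq) {
  cls <- classify_chars(seq)
  runs_from_classes(cls, c("soft", "hard"))
}

# per-character class: hard (N/n), soft (lowercase), upper (ACGT), other
classify_chars <- function(seq) {
  if (nchar(seq) == 0) return(character(0))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  cls <- rep("other", length(ch))
  cls[ch %in% c("A", "C", "G", "T")] <- "upper"
  cls[ch != toupper(ch)] <- "soft"
  cls[ch %in% c("N", "n")] <- "hard"
  cls
}

runs_from_classes <- function(cls, keep) {
  if (length(cls) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  r <- rle(cls)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  sel <- r$values %in% keep
  data.frame(start = start[sel], end = end[sel], kind = r$values[sel],
             stringsAsFactors = FALSE)
}

#' Soft-mask short unmasked islands between masked runs
#'
#' After the polishing sweep, every maximal uppercase ACGT run shorter than
#' the lowest sweep k whose immediate left and right neighbors are both
#' soft-masked runs is itself lowercased, so the gap filler treats the whole
#' stretch as one problem. The rule is applied over the original run
#' structure and re-evaluated to a fixpoint, making it order-independent.
#' Sequence boundaries and hard (`N`) runs do not count as masking flanks:
#' a terminal island, or one beside an N-run, is kept.
#'
#' @param seq A sequence string.
#' @param k_min The lowest k of the sweep.
#' @return The sequence with qualifying islands lowercased; all other
#'   characters unchanged.
#' @export
consolidate_mask <- function(seq, k_min) {
  stopifnot(k_min >= 1)
  repeat {
    cls <- classify_chars(seq)
    if (length(cls) == 0) return(seq)
    r <- rle(cls)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    to_mask <- which(
      r$values == "upper" & r$lengths < k_min &
        seq_along(r$values) > 1L & seq_along(r$values) < length(r$values) &
        c("", utils::head(r$values, -1)) == "soft" &
        c(r$values[-1], "") == "soft"
    )
    if (length(to_mask) == 0) return(seq)
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    for (t in to_mask) {
      idx <- (starts[t] + 1L):ends[t]
      ch[idx] <- tolower(ch[idx])
    }
    seq <- paste(ch, collapse = "")
  }
}
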