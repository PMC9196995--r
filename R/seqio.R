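#' Read a FASTA file into a table of sequence records
#'
#' Reads single- or multi-line FASTA. Case and `N` characters are preserved
#' byte-for-byte: lowercase letters carry the soft-masking channel used by
#' the polishing pipeline and are never normalized on input or output.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with character columns `id` (first
#'   whitespace-delimited word of the header), `desc` (remainder of the
#'   header, `""` when absent) and `seq`, one row per record, in file order.
#'   An empty file yields a zero-row table.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  if (file.size(path) == 0) {
    return(data.frame(id = character(), desc = character(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  first <- readChar(path, 1L, useBytes = TRUE)
  if (!identical(first, ">")) {
    stop("FASTA format error in ", path, ": sequence body before first '>'",
         call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) {
      stop("FASTA format error in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  data.frame(id = id, desc = desc, seq = as.character(set),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write sequence records as wrapped FASTA
#'
#' @param records A `data.frame` with columns `id`, `seq` and optionally
#'   `desc`, as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line width for wrapping sequence bodies (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), width >= 1L)
  desc <- if ("desc" %in% names(records)) records$desc else
    rep("", nrow(records))
  headers <- ifelse(is.na(desc) | desc == "", records$id,
                    paste(records$id, desc))
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  invisible(path)
}

#' Stream read sequences from FASTQ files
#'
#' Consumes one or more FASTQ files (plain or gzip-compressed, detected
#' automatically) and returns the read sequences only; names and qualities
#' are discarded because only k-mer content matters downstream. Pairing is
#' irrelevant to k-mer extraction, so mate files are simply listed.
#'
#' @param paths Character vector of FASTQ paths, consumed in order.
#' @return Character vector of read sequences in file order.
#' @export
stream_reads <- function(paths) {
  stopifnot(length(paths) >= 1L)
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
    con <- gzfile(p, "rt")  # transparently handles plain text too
    n_lines <- 0L
    repeat {
      chunk <- readLines(con, n = 65536L)
      if (length(chunk) == 0L) break
      n_lines <- n_lines + length(chunk)
    }
    close(con)
    if (n_lines %% 4L != 0L) {
      stop("FASTQ format error in ", p, ": truncated record ",
           n_lines %/% 4L + 1L, call. = FALSE)
    }
    set <- tryCatch(
      Biostrings::readBStringSet(p, format = "fastq"),
      error = function(e) {
        stop("FASTQ format error in ", p, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    out[[i]] <- as.character(set)
  }
  unlist(out, use.names = FALSE) %||% character()
}
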