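#' Read transcript sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file into a data frame
#' of transcript records. The identifier of each record is the first
#' whitespace-delimited token of its header line; the remainder of the header
#' is retained as a description but ignored by the rest of the pipeline.
#' Sequences are uppercased on read. In nucleotide mode `U` is mapped to `T`
#' and the permitted alphabet is `A C G T N`; in protein mode the 20 standard
#' amino-acid letters plus `X` are permitted.
#'
#' @param path Path to an existing FASTA file.
#' @param mode `"nucleotide"` or `"protein"`; selects the permitted alphabet.
#' @param species Optional species label attached to every record.
#'
#' @return A data frame with columns `transcript_id`, `sequence`, `species`
#'   and `description`, one row per record in file order.
#'
#' @details Duplicate identifiers and characters outside the permitted
#'   alphabet are hard errors (the error message names the offending
#'   identifier or line number); empty sequences are rejected.
#'
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1 first", "ac", "gt"), fa)
#' read_fasta(fa)
#'
#' @export
read_fasta <- function(path, mode = c("nucleotide", "protein"),
                       species = NA_character_) {
  mode <- match.arg(mode)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  alphabet_re <- if (mode == "nucleotide") "^[ACGTN]*$" else "^[ACDEFGHIKLMNPQRSTVWYX]*$"

  ids <- character(0)
  desc <- character(0)
  seqs <- character(0)
  chunks <- character(0)   # sequence lines of the current record
  open <- FALSE

  flush_record <- function() {
    seq <- paste0(chunks, collapse = "")
    if (!nzchar(seq)) {
      stop("empty sequence for record '", ids[length(ids)], "' in ", path,
           call. = FALSE)
    }
    seqs[[length(seqs) + 1L]] <<- seq
    chunks <<- character(0)
  }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (startsWith(line, ">")) {
      if (open) flush_record()
      header <- sub("^>\\s*", "", line)
      id <- sub("\\s.*$", "", header)
      if (!nzchar(id)) {
        stop("FASTA header without identifier at line ", i, " of ", path,
             call. = FALSE)
      }
      if (id %in% ids) {
        stop("duplicate FASTA identifier '", id, "' in ", path, call. = FALSE)
      }
      ids <- c(ids, id)
      desc <- c(desc, sub("^\\S+\\s*", "", header))
      open <- TRUE
    } else {
      if (!open) {
        if (grepl("^\\s*$", line)) next
        stop("sequence data before first FASTA header at line ", i, " of ",
             path, call. = FALSE)
      }
      s <- toupper(gsub("\\s", "", line))
      if (mode == "nucleotide") s <- chartr("U", "T", s)
      if (!grepl(alphabet_re, s)) {
        bad <- gsub(sub("\\*\\$$", "", sub("^\\^", "", alphabet_re)), "", s)
        stop("illegal ", mode, " character '", substr(bad, 1L, 1L),
             "' at line ", i, " of ", path, call. = FALSE)
      }
      if (nzchar(s)) chunks <- c(chunks, s)
    }
  }
  if (open) flush_record()

  data.frame(transcript_id = ids,
             sequence = seqs,
             species = rep(species, length(ids)),
             description = desc,
             stringsAsFactors = FALSE)
}

#' Write transcript sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: writes one record per row, wrapping sequence
#' lines at `width` characters. Descriptions, when present and non-empty, are
#' appended to the header after a space.
#'
#' @param transcripts Data frame with columns `transcript_id` and `sequence`
#'   (optionally `description`), as returned by [read_fasta()].
#' @param path Output path.
#' @param width Sequence line width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(transcripts, path, width = 60L) {
  stopifnot(is.data.frame(transcripts),
            all(c("transcript_id", "sequence") %in% names(transcripts)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  has_desc <- "description" %in% names(transcripts)
  for (i in seq_len(nrow(transcripts))) {
    header <- paste0(">", transcripts$transcript_id[[i]])
    if (has_desc && !is.na(transcripts$description[[i]]) &&
        nzchar(transcripts$description[[i]])) {
      header <- paste(header, transcripts$description[[i]])
    }
    writeLines(header, con)
    seq <- transcripts$sequence[[i]]
    starts <- seq.int(1L, nchar(seq), by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1L, nchar(seq))), con)
  }
  invisible(path)
}
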