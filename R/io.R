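#' Read transcripts from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file, takes the
#' token before the first whitespace of each header as the transcript id,
#' and normalizes the sequences (uppercase, U to T). Duplicate ids are an
#' error.
#'
#' @param path Path to a FASTA file (DNA or RNA alphabet).
#' @return A transcript data frame with `label = "unlabeled"`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(ss), "[[:space:]]+"), `[[`, character(1L), 1L)
  as_transcripts(data.frame(id = ids, seq = as.character(ss),
                            stringsAsFactors = FALSE))
}

#' Write transcripts to a FASTA file
#'
#' @param transcripts Transcript data frame.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(transcripts, path, width = 70L) {
  transcripts <- as_transcripts(transcripts, normalize = FALSE)
  ss <- Biostrings::BStringSet(stats::setNames(transcripts$seq,
                                               transcripts$id))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a transcript label table
#'
#' @param path TSV with header columns `transcript_id` and `label`
#'   (values `coding` or `noncoding`).
#' @return A data frame with those two columns.
#' @export
read_label_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("transcript_id", "label") %in% names(tab)))
  if (anyDuplicated(tab$transcript_id)) stop("duplicated ids in label table")
  bad <- !(tab$label %in% c("coding", "noncoding"))
  if (any(bad)) stop("invalid labels: ",
                     paste(unique(tab$label[bad]), collapse = ", "))
  tab[, c("transcript_id", "label")]
}

#' Assign coding/noncoding labels to transcripts
#'
#' With a label table, every transcript id must be present in it. Without
#' one, the RefSeq accession-prefix rule is applied: ids starting `NM_`
#' are coding, `NR_` noncoding, anything else stays unlabeled (and is
#' excluded from the class frequency distributions, with a message giving
#' the count).
#'
#' @param transcripts Transcript data frame.
#' @param table Optional label table (see [read_label_table()]).
#' @return The transcript data frame with its `label` column filled in.
#' @export
infer_labels <- function(transcripts, table = NULL) {
  transcripts <- as_transcripts(transcripts, normalize = FALSE)
  if (!is.null(table)) {
    missing <- setdiff(transcripts$id, table$transcript_id)
    if (length(missing)) {
      stop("ids missing from label table: ",
           paste(utils::head(missing, 10L), collapse = ", "))
    }
    transcripts$label <-
      table$label[match(transcripts$id, table$transcript_id)]
  } else {
    transcripts$label <- ifelse(
      startsWith(transcripts$id, "NM_"), "coding",
      ifelse(startsWith(transcripts$id, "NR_"), "noncoding", "unlabeled"))
    n_un <- sum(transcripts$label == "unlabeled")
    if (n_un > 0L) {
      message(n_un, " transcript(s) match neither NM_ nor NR_ and stay unlabeled")
    }
  }
  transcripts
}

#' Read a Ka/Ks table
#'
#' @param path TSV with header columns `transcript_id`, `ka`, `ks`.
#' @return A data frame with those columns.
#' @export
read_kaks_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("transcript_id", "ka", "ks") %in% names(tab)))
  tab
}

#' Write a per-transcript profile table
#'
#' Tab-separated with a header line; undefined values are written as
#' `NA`; scores are rounded half-up to 3 decimals for display.
#'
#' @param profiles Profile data frame from [profile_transcripts()].
#' @param path Output path, or `""` for standard output.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profiles, path) {
  out <- profiles
  out$dominance <- round_half_up(out$dominance, 3L)
  out$coverage <- round_half_up(out$coverage, 3L)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a profile table written by [write_profile_tsv()]
#' @param path Input path.
#' @return A profile data frame.
#' @export
read_profile_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}
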