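.stop_codons <- c("TAA", "TAG", "TGA")

#' Enumerate ORFs in the three forward reading frames
#'
#' An ORF is a segment that begins at `ATG` and ends at the first in-frame
#' stop codon (`TAA`, `TAG`, or `TGA`), read 5' to 3'. After a stop codon
#' closes an ORF, scanning resumes at the next codon, so ORFs within one
#' frame never overlap (internal `ATG`s do not open nested ORFs). An `ATG`
#' with no downstream in-frame stop yields no ORF, and the reverse
#' complement is never scanned. Codons containing an ambiguity code match
#' neither `ATG` nor a stop.
#'
#' @param seq A single normalized sequence (see [normalize_sequence()]).
#' @return A data frame with one row per ORF and columns `frame` (0/1/2,
#'   5' offset of the reading frame), `start` (0-based nucleotide offset
#'   of the `A` of `ATG`), and `aa_length` (amino acids, stop excluded).
#'   Zero rows when the sequence contains no ORF.
#' @examples
#' scan_orfs("ATGTAA")     # one ORF: frame 0, start 0, 1 aa
#' scan_orfs("ATGAAATGA")  # one ORF: frame 0, start 0, 2 aa
#' @export
scan_orfs <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  n <- nchar(seq)
  empty <- data.frame(frame = integer(), start = integer(),
                      aa_length = integer())
  out <- vector("list", 3L)
  for (frame in 0:2) {
    n_codons <- (n - frame) %/% 3L
    if (n_codons < 2L) next
    pos <- frame + 3L * (seq_len(n_codons) - 1L) + 1L
    codons <- substring(seq, pos, pos + 2L)
    stops <- which(codons %in% .stop_codons)
    if (!length(stops)) next
    augs <- which(codons == "ATG")
    if (!length(augs)) next
    # Between consecutive stops, the first ATG (if any) opens the ORF
    # that the later stop closes; scanning then resumes past the stop.
    prev <- c(0L, stops[-length(stops)])
    cand_i <- findInterval(prev, augs) + 1L
    ok <- cand_i <= length(augs)
    cand <- rep(NA_integer_, length(stops))
    cand[ok] <- augs[cand_i[ok]]
    keep <- which(!is.na(cand) & cand < stops)
    if (!length(keep)) next
    out[[frame + 1L]] <- data.frame(
      frame = frame,
      start = frame + 3L * (cand[keep] - 1L),
      aa_length = stops[keep] - cand[keep]
    )
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$frame, res$start), , drop = FALSE]
}

#' Scan a set of transcripts for ORFs
#'
#' @param transcripts A transcript data frame with columns `id` and `seq`
#'   (normalized bases), e.g. from [read_fasta()] or [as_transcripts()].
#' @return A data frame with columns `transcript_id`, `frame`, `start`,
#'   `aa_length`, containing all ORFs of all transcripts.
#' @export
scan_transcripts <- function(transcripts) {
  transcripts <- as_transcripts(transcripts)
  res <- lapply(seq_len(nrow(transcripts)), function(i) {
    orfs <- scan_orfs(transcripts$seq[i])
    if (!nrow(orfs)) return(NULL)
    cbind(transcript_id = transcripts$id[i], orfs)
  })
  res <- res[!vapply(res, is.null, logical(1L))]
  if (!length(res)) {
    return(data.frame(transcript_id = character(), frame = integer(),
                      start = integer(), aa_length = integer()))
  }
  do.call(rbind, res)
}
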