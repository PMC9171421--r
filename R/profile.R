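#' ORF dominance from ORF lengths
#'
#' ORF dominance is the length of the primary ORF (the longest ORF over
#' the three forward frames) divided by the sum of all ORF lengths of the
#' transcript. A single-ORF transcript has dominance 1; when the secondary
#' ORF lengths sum to the primary ORF length the dominance is 0.5. Ties
#' for the longest ORF need no special treatment: the numerator is the
#' shared maximum and the denominator the sum of all lengths. With no ORF
#' the score is undefined (`NA`).
#'
#' @param aa_lengths Integer vector of ORF amino-acid lengths (stop codon
#'   excluded), in any order.
#' @return Dominance in (0, 1], or `NA_real_` for an empty vector.
#' @examples
#' dominance_from_lengths(c(109, 69, 8, 6))  # 0.5677...
#' dominance_from_lengths(42)                # 1
#' @export
dominance_from_lengths <- function(aa_lengths) {
  if (!length(aa_lengths)) return(NA_real_)
  if (any(is.na(aa_lengths)) || any(aa_lengths < 1)) {
    stop("ORF lengths must be positive")
  }
  max(aa_lengths) / sum(aa_lengths)
}

#' Per-transcript ORF profiles
#'
#' Summarizes the ORF content of each transcript: number of ORFs, primary
#' ORF (pORF) length, summed secondary ORF (secORF) length, ORF dominance,
#' and ORF coverage. Coverage is the nucleotide span of the pORF including
#' its stop codon divided by transcript length, capped at 1. Transcripts
#' with no ORF get `NA` dominance and coverage.
#'
#' @param transcripts A transcript data frame (see [as_transcripts()]).
#' @param orfs Optional precomputed ORF table from [scan_transcripts()];
#'   scanned on the fly when omitted.
#' @return A data frame with columns `transcript_id`, `label`,
#'   `transcript_length`, `n_orfs`, `porf_aa`, `sum_secorf_aa`,
#'   `dominance`, `coverage`.
#' @export
profile_transcripts <- function(transcripts, orfs = NULL) {
  transcripts <- as_transcripts(transcripts)
  if (is.null(orfs)) orfs <- scan_transcripts(transcripts)
  lens <- split(orfs$aa_length, factor(orfs$transcript_id,
                                       levels = transcripts$id))
  n_orfs <- vapply(lens, length, integer(1L))
  porf <- vapply(lens, function(v) if (length(v)) max(v) else NA_real_,
                 numeric(1L))
  total <- vapply(lens, sum, numeric(1L))
  tx_len <- nchar(transcripts$seq)
  prof <- data.frame(
    transcript_id = transcripts$id,
    label = transcripts$label,
    transcript_length = tx_len,
    n_orfs = n_orfs,
    porf_aa = porf,
    sum_secorf_aa = ifelse(n_orfs > 0L, total - porf, NA_real_),
    dominance = ifelse(n_orfs > 0L, porf / total, NA_real_),
    coverage = ifelse(n_orfs > 0L, pmin((3 * porf + 3) / tx_len, 1), NA_real_),
    stringsAsFactors = FALSE
  )
  rownames(prof) <- NULL
  prof
}

#' Apply the noncoding-transcript filters
#'
#' Removes, from the noncoding class only, transcripts shorter than
#' `min_nt` nucleotides or with a pORF shorter than `min_porf_aa` amino
#' acids (strictly-less-than exclusion; transcripts exactly at a threshold
#' are kept). Profiles without any ORF (undefined dominance) are removed
#' from every class.
#'
#' @param profiles A profile data frame from [profile_transcripts()].
#' @param min_nt Minimum transcript length in nucleotides (default 200).
#' @param min_porf_aa Minimum pORF length in amino acids (default 20).
#' @return The filtered profile data frame.
#' @export
apply_noncoding_filters <- function(profiles, min_nt = 200L,
                                    min_porf_aa = 20L) {
  stopifnot(min_nt > 0, min_porf_aa > 0)
  keep <- profiles$n_orfs > 0L
  nc <- profiles$label == "noncoding"
  keep <- keep & !(nc & (profiles$transcript_length < min_nt |
                           !is.na(profiles$porf_aa) &
                           profiles$porf_aa < min_porf_aa))
  out <- profiles[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
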