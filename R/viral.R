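#' Score a viral genome against its bona fide ORF annotation
#'
#' Extends ORF dominance to multi-ORF viral genomes. All ORFs of the
#' genome are enumerated with [scan_orfs()]; the annotated bona fide ORFs
#' (vORFs) are removed from the pool and the rest are the genome's
#' secondary ORFs. The vORF score is the summed annotated vORF length
#' divided by the summed length of all ORFs:
#' `score = sum(l_vORF) / (sum(l_vORF) + sum(l_secORF))`.
#'
#' Matching uses frame plus stop-codon position when the annotation gives
#' coordinates (annotated CDSs may start at an internal ATG relative to
#' the scanner's first-ATG convention, but share the stop), and falls
#' back to amino-acid-length matching for a lengths-only annotation. An
#' annotated entry that matches no predicted ORF triggers a warning and
#' still contributes its length to the vORF sum.
#'
#' @param genome A single transcript (data frame row, named character of
#'   length 1, or anything [as_transcripts()] accepts with one record).
#' @param annotation Either a BED-like data frame with columns `start`,
#'   `end` (0-based half-open nucleotide span including the stop codon)
#'   and `frame`, or a lengths-only data frame with column `aa_length`.
#' @return Object of class `viral_score`: list with `genome_id`,
#'   `sum_vorf`, `sum_secorf`, `score`, and the secORF length vector.
#' @export
vorf_score <- function(genome, annotation) {
  genome <- as_transcripts(genome)
  if (nrow(genome) != 1L) stop("'genome' must be a single sequence")
  if (!is.data.frame(annotation) || !nrow(annotation)) {
    stop("annotation is empty")
  }
  orfs <- scan_orfs(genome$seq)
  used <- rep(FALSE, nrow(orfs))
  if (all(c("start", "end", "frame") %in% names(annotation))) {
    vlens <- (annotation$end - annotation$start) / 3 - 1
    if (any(vlens < 1 | vlens != round(vlens))) {
      stop("annotated spans must be whole codons covering >= 2 codons")
    }
    if (any(annotation$start < 0 | annotation$end > nchar(genome$seq))) {
      stop("annotated span outside the genome")
    }
    ann_stop <- annotation$end - 3L       # 0-based offset of the stop codon
    for (i in seq_len(nrow(annotation))) {
      hit <- which(!used & orfs$frame == annotation$frame[i] &
                     orfs$start + 3L * orfs$aa_length == ann_stop[i])
      if (length(hit)) {
        used[hit[1L]] <- TRUE
      } else {
        warning(sprintf("annotated vORF span [%d, %d) frame %d matches no predicted ORF",
                        annotation$start[i], annotation$end[i],
                        annotation$frame[i]))
      }
    }
  } else if ("aa_length" %in% names(annotation)) {
    vlens <- annotation$aa_length
    if (any(vlens < 1)) stop("annotated vORF lengths must be >= 1 aa")
    for (i in seq_along(vlens)) {
      hit <- which(!used & orfs$aa_length == vlens[i])
      if (length(hit)) {
        used[hit[1L]] <- TRUE
      } else {
        warning(sprintf("annotated vORF length %s matches no predicted ORF",
                        format(vlens[i])))
      }
    }
  } else {
    stop("annotation needs columns start/end/frame or aa_length")
  }
  sec <- orfs$aa_length[!used]
  sum_v <- sum(vlens)
  structure(list(genome_id = genome$id,
                 sum_vorf = sum_v,
                 sum_secorf = sum(sec),
                 secorf_lengths = sec,
                 score = sum_v / (sum_v + sum(sec))),
            class = "viral_score")
}

#' @export
print.viral_score <- function(x, ...) {
  cat(sprintf("%s: sum vORF = %s aa, sum secORF = %s aa, vORF score = %.3f\n",
              x$genome_id, format(x$sum_vorf), format(x$sum_secorf), x$score))
  invisible(x)
}

#' Read a viral ORF annotation table
#'
#' Either BED-like (`genome_id`, `start`, `end`, `frame`; 0-based
#' half-open, stop codon included) or lengths-only (`genome_id`,
#' `aa_length`).
#'
#' @param path TSV path with a header line.
#' @return A data frame.
#' @export
read_vorf_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  ok <- all(c("genome_id", "start", "end", "frame") %in% names(tab)) ||
    all(c("genome_id", "aa_length") %in% names(tab))
  if (!ok) {
    stop("annotation needs columns genome_id,start,end,frame or genome_id,aa_length")
  }
  tab
}
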