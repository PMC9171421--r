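#' Uniform-random null-sequence controls
#'
#' For every input transcript, generates one control of the same length
#' in which each base is drawn i.i.d. uniformly from A/C/G/T. This is the
#' harsher of the two null models: it preserves only length, not base
#' composition.
#'
#' @param transcripts Transcript data frame.
#' @param seed Integer RNG seed (mandatory, for reproducibility).
#' @param suffix Appended to each control id (default `"_rand"`).
#' @return A transcript data frame of controls (labels carried over).
#' @export
uniform_random_control <- function(transcripts, seed, suffix = "_rand") {
  transcripts <- as_transcripts(transcripts)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))
  seqs <- vapply(nchar(transcripts$seq), function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1L))
  data.frame(id = paste0(transcripts$id, suffix), seq = seqs,
             label = transcripts$label, stringsAsFactors = FALSE)
}

#' Shuffled null-sequence controls
#'
#' Randomly permutes the bases of each transcript, preserving its exact
#' base composition (the A/C/G/T multiset) but destroying codon
#' structure.
#'
#' @inheritParams uniform_random_control
#' @param suffix Appended to each control id (default `"_shuf"`).
#' @return A transcript data frame of controls.
#' @export
shuffle_control <- function(transcripts, seed, suffix = "_shuf") {
  transcripts <- as_transcripts(transcripts)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))
  seqs <- vapply(transcripts$seq, function(s) {
    paste(sample(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
  data.frame(id = paste0(transcripts$id, suffix), seq = seqs,
             label = transcripts$label, stringsAsFactors = FALSE)
}

.non_stop_codons <- local({
  b <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all_codons, c("TAA", "TAG", "TGA"))
})

#' Generate a labeled synthetic transcript fixture
#'
#' Emulates the qualitative contrast between coding and noncoding
#' transcript sets: each coding-like transcript carries a single long
#' clean ORF (ATG, a stop-free codon run, then a stop codon) spanning at
#' least half — by default 50–90% — of its length, embedded at a random
#' offset in otherwise uniform-random sequence; noncoding-like
#' transcripts are entirely uniform random. Ids carry `NM_`/`NR_`
#' prefixes so the accession-prefix label rule also applies to fixtures.
#'
#' @param n_coding,n_noncoding Numbers of transcripts per class.
#' @param length_range Inclusive nucleotide length range, minimum 200
#'   (default `c(500, 3000)`, a typical mRNA/lncRNA scale).
#' @param seed Integer RNG seed.
#' @param orf_frac_range Fraction of the transcript the embedded ORF
#'   spans, drawn uniformly per transcript (default `c(0.5, 0.9)`).
#' @return A labeled transcript data frame.
#' @export
synthesize_fixture <- function(n_coding, n_noncoding,
                               length_range = c(500L, 3000L), seed,
                               orf_frac_range = c(0.5, 0.9)) {
  stopifnot(n_coding >= 0L, n_noncoding >= 0L, length(length_range) == 2L,
            is.numeric(seed), length(seed) == 1L)
  if (min(length_range) < 200L) {
    stop("lengths below 200 nt cannot host a fixture ORF; raise length_range")
  }
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(n) {
    if (n <= 0L) return("")
    paste(sample(bases, n, replace = TRUE), collapse = "")
  }
  make_coding <- function(len) {
    frac <- stats::runif(1L, orf_frac_range[1L], orf_frac_range[2L])
    aa <- max(1L, ceiling((frac * len - 3) / 3))   # span 3*aa + 3 >= frac*len
    span <- 3L * aa + 3L
    if (span > len) {
      aa <- (len - 3L) %/% 3L
      span <- 3L * aa + 3L
    }
    offset <- sample.int(len - span + 1L, 1L) - 1L
    body <- if (aa > 1L) {
      paste(sample(.non_stop_codons, aa - 1L, replace = TRUE), collapse = "")
    } else ""
    paste0(rand_seq(offset), "ATG", body,
           sample(c("TAA", "TAG", "TGA"), 1L),
           rand_seq(len - offset - span))
  }
  lens_c <- if (n_coding > 0L)
    sample(length_range[1L]:length_range[2L], n_coding, replace = TRUE)
  else integer()
  lens_n <- if (n_noncoding > 0L)
    sample(length_range[1L]:length_range[2L], n_noncoding, replace = TRUE)
  else integer()
  tx <- data.frame(
    id = c(sprintf("NM_synth%05d", seq_len(n_coding)),
           sprintf("NR_synth%05d", seq_len(n_noncoding))),
    seq = c(vapply(lens_c, make_coding, character(1L)),
            vapply(lens_n, rand_seq, character(1L))),
    label = rep(c("coding", "noncoding"), c(n_coding, n_noncoding)),
    stringsAsFactors = FALSE
  )
  rownames(tx) <- NULL
  tx
}
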