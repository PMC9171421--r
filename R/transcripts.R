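#' Coerce input to a transcript data frame
#'
#' The package represents a transcript set as a plain data frame with
#' columns `id`, `seq` (normalized bases) and `label` (one of `"coding"`,
#' `"noncoding"`, `"unlabeled"`). Accepts such a data frame, a named
#' character vector of sequences, or a `Biostrings::XStringSet`.
#'
#' @param x Input to coerce.
#' @param normalize Normalize the sequences (uppercase, U to T)? Default
#'   `TRUE`.
#' @return A transcript data frame.
#' @export
as_transcripts <- function(x, normalize = TRUE) {
  if (is.data.frame(x)) {
    if (!all(c("id", "seq") %in% names(x))) {
      stop("transcript data frame needs columns 'id' and 'seq'")
    }
    tx <- data.frame(id = as.character(x$id), seq = as.character(x$seq),
                     label = if ("label" %in% names(x))
                       as.character(x$label) else "unlabeled",
                     stringsAsFactors = FALSE)
  } else if (methods::is(x, "XStringSet")) {
    tx <- data.frame(id = names(x), seq = as.character(x),
                     label = "unlabeled", stringsAsFactors = FALSE)
  } else if (is.character(x)) {
    if (is.null(names(x))) stop("character input must be named by transcript id")
    tx <- data.frame(id = names(x), seq = unname(x), label = "unlabeled",
                     stringsAsFactors = FALSE)
  } else {
    stop("cannot interpret 'x' as a transcript set")
  }
  if (anyDuplicated(tx$id)) {
    stop("duplicated transcript ids: ",
         paste(unique(tx$id[duplicated(tx$id)]), collapse = ", "))
  }
  if (any(!nzchar(tx$id))) stop("empty transcript id")
  bad <- !(tx$label %in% c("coding", "noncoding", "unlabeled"))
  if (any(bad)) {
    stop("invalid label(s): ", paste(unique(tx$label[bad]), collapse = ", "))
  }
  if (normalize) tx$seq <- vapply(tx$seq, normalize_sequence, character(1L),
                                  USE.NAMES = FALSE)
  rownames(tx) <- NULL
  tx
}

#' @keywords internal
round_half_up <- function(x, digits = 3L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
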