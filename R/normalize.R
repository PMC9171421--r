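# Accepted alphabet: the four bases, N, and the IUPAC ambiguity codes.
.base_alphabet <- c("A", "C", "G", "T",
                    "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Normalize a nucleotide sequence
#'
#' Uppercases the sequence and converts RNA to DNA representation
#' (`U` to `T`) so that downstream ORF scanning works on a single
#' alphabet. Ambiguity codes (`N`, `R`, `Y`, ...) are retained; any
#' other character is an error.
#'
#' @param raw A single non-empty nucleotide string (DNA or RNA, any case).
#' @return The normalized string, same length as `raw`, containing only
#'   `A`/`C`/`G`/`T` and IUPAC ambiguity codes.
#' @examples
#' normalize_sequence("augTaa")  # "ATGTAA"
#' @export
normalize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw)) {
    stop("'raw' must be a single non-empty nucleotide string")
  }
  s <- chartr("U", "T", toupper(raw))
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% .base_alphabet))
  if (length(bad)) {
    stop(sprintf("illegal character '%s' at position %d", chars[bad[1L]], bad[1L]))
  }
  s
}
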