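# Independent oracles, deliberately written with different algorithms
# than the package internals.

# Character-walk ORF enumeration: per frame, walk codon by codon; an ATG
# opens an ORF, the first stop closes it and the walk resumes after the
# stop. Returns the same columns as scan_orfs().
oracle_scan <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  rows <- list()
  for (f in 0:2) {
    i <- f + 1L
    open <- NA_integer_
    while (i + 2L <= length(chars)) {
      codon <- paste(chars[i:(i + 2L)], collapse = "")
      if (is.na(open)) {
        if (codon == "ATG") open <- i
      } else if (codon %in% c("TAA", "TAG", "TGA")) {
        rows[[length(rows) + 1L]] <-
          data.frame(frame = f, start = open - 1L,
                     aa_length = (i - open) %/% 3L)
        open <- NA_integer_
      }
      i <- i + 3L
    }
  }
  if (!length(rows)) {
    return(data.frame(frame = integer(), start = integer(),
                      aa_length = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$frame, out$start), , drop = FALSE]
}

# Closed-form simple linear regression via the normal equations.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  resid <- y - (slope * x + intercept)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Direct per-bin tally with explicit interval comparisons.
oracle_bin_counts <- function(scores) {
  edges_lo <- seq(0, 0.9, by = 0.1)
  edges_hi <- seq(0.1, 1.0, by = 0.1)
  vapply(seq_len(10L), function(k) {
    if (k < 10L) sum(scores >= edges_lo[k] & scores < edges_hi[k])
    else sum(scores >= 0.9 & scores <= 1.0)
  }, integer(1L))
}

random_sequence <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
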