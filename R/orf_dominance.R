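#' ORF dominance analysis of a labeled transcript set
#'
#' The main entry point. Scans every transcript in the three forward
#' reading frames, computes per-transcript ORF dominance (and coverage),
#' applies the noncoding filters, bins the coding and noncoding scores
#' into the ten-class relative-frequency distributions f(x) and g(x),
#' and derives the population statistics: the protein-coding potential
#' table F(x) = f/(f+g), the histogram overlap O, and the linear
#' regression of F(x) on x for x <= `x_max`.
#'
#' @param x Transcripts: a data frame with columns `id`, `seq` and
#'   optionally `label`, a named character vector, an `XStringSet`, or a
#'   path to a FASTA file.
#' @param labels Optional label table (columns `transcript_id`, `label`).
#'   When neither `labels` nor a `label` column is supplied, the
#'   `NM_`/`NR_` accession-prefix rule is used.
#' @param score_kind Score the distributions are built on:
#'   `"dominance"` (default) or `"coverage"`.
#' @param min_nt,min_porf_aa Noncoding filters (defaults 200 nt, 20 aa);
#'   see [apply_noncoding_filters()].
#' @param x_max Upper bin median used in the regression (default 0.65).
#' @param min_bin_count Minimum noncoding transcripts per regression bin
#'   (default 5).
#' @param min_noncoding Minimum noncoding transcripts for the overlap
#'   score (default 3).
#' @return An object of class `orf_dominance`: a list with elements
#'   `profiles` (all transcripts), `profiles_used` (after filtering),
#'   `f`, `g` (binned distributions), `potential`, `overlap`, `fit`
#'   (`NULL` when too few usable bins), `n_excluded`, and the parameters.
#'   Methods: `print`, `summary`, `coef`, `predict`, `plot`, `residuals`.
#' @examples
#' tx <- synthesize_fixture(60, 60, c(500, 1500), seed = 1)
#' od <- orf_dominance(tx)
#' od
#' predict(od, 0.35)
#' @export
orf_dominance <- function(x, labels = NULL,
                          score_kind = c("dominance", "coverage"),
                          min_nt = 200L, min_porf_aa = 20L, x_max = 0.65,
                          min_bin_count = 5L, min_noncoding = 3L) {
  score_kind <- match.arg(score_kind)
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x)) {
    x <- read_fasta(x)
  }
  tx <- as_transcripts(x)
  if (!is.null(labels) || all(tx$label == "unlabeled")) {
    tx <- infer_labels(tx, labels)
  }
  profiles <- profile_transcripts(tx)
  used <- apply_noncoding_filters(profiles, min_nt = min_nt,
                                  min_porf_aa = min_porf_aa)
  used <- used[used$label != "unlabeled", , drop = FALSE]
  if (!nrow(used)) stop("no labeled transcript with an ORF survives filtering")
  score <- used[[score_kind]]
  f <- bin_scores(score[used$label == "coding"], score_kind)
  g <- bin_scores(score[used$label == "noncoding"], score_kind)
  if (f$total < 1L || g$total < 1L) {
    stop("both a coding and a noncoding class are required")
  }
  pot <- coding_potential(f, g)
  ov <- tryCatch(overlap_score(f, g, min_noncoding = min_noncoding),
                 error = function(e) {
                   warning(conditionMessage(e)); NULL
                 })
  fit <- tryCatch(fit_potential_regression(pot, x_max = x_max,
                                           min_bin_count = min_bin_count),
                  error = function(e) NULL)
  structure(list(profiles = profiles, profiles_used = used,
                 f = f, g = g, potential = pot, overlap = ov, fit = fit,
                 n_excluded = nrow(profiles) - nrow(used),
                 params = list(score_kind = score_kind, min_nt = min_nt,
                               min_porf_aa = min_porf_aa, x_max = x_max,
                               min_bin_count = min_bin_count,
                               min_noncoding = min_noncoding)),
            class = "orf_dominance")
}

#' @export
print.orf_dominance <- function(x, ...) {
  cat("ORF dominance analysis\n")
  cat(sprintf("  %d transcripts scored (%d coding, %d noncoding used; %d excluded)\n",
              nrow(x$profiles), x$f$total, x$g$total, x$n_excluded))
  if (!is.null(x$overlap)) {
    cat(sprintf("  overlap O_%s = %.3f\n",
                if (x$params$score_kind == "dominance") "dom" else "cov",
                x$overlap$O))
  }
  if (!is.null(x$fit)) {
    cat("  "); print(x$fit)
  } else {
    cat("  regression: not fitted (too few usable bins)\n")
  }
  invisible(x)
}

#' @export
summary.orf_dominance <- function(object, ...) {
  tab <- data.frame(x = object$f$mids,
                    n_coding = object$f$counts, f = object$f$freq,
                    n_noncoding = object$g$counts, g = object$g$freq,
                    F = object$potential$potential)
  structure(list(table = tab, overlap = object$overlap, fit = object$fit,
                 params = object$params,
                 n_used = c(coding = object$f$total,
                            noncoding = object$g$total),
                 n_excluded = object$n_excluded),
            class = "summary.orf_dominance")
}

#' @export
print.summary.orf_dominance <- function(x, ...) {
  cat("ORF dominance analysis summary\n")
  cat(sprintf("  transcripts used: %d coding, %d noncoding (%d excluded)\n",
              x$n_used[["coding"]], x$n_used[["noncoding"]], x$n_excluded))
  tab <- x$table
  tab$f <- round(tab$f, 4); tab$g <- round(tab$g, 4)
  tab$F <- round(tab$F, 4)
  print(tab, row.names = FALSE)
  if (!is.null(x$overlap)) cat(sprintf("  overlap O = %.3f\n", x$overlap$O))
  if (!is.null(x$fit)) { cat("  "); print(x$fit) }
  invisible(x)
}

#' @export
coef.orf_dominance <- function(object, ...) {
  if (is.null(object$fit)) stop("no regression fit available")
  coef(object$fit)
}

#' Predict coding potential from a fitted analysis
#'
#' @param object An [orf_dominance()] object with a regression fit.
#' @param newdata Dominance (or coverage) values; defaults to the bin
#'   medians used in the fit.
#' @param ... Unused.
#' @return Predicted coding potential in \[0, 1\].
#' @export
predict.orf_dominance <- function(object, newdata = NULL, ...) {
  if (is.null(object$fit)) stop("no regression fit available")
  if (is.null(newdata)) newdata <- object$fit$bins_used
  predict_potential(object$fit, newdata)
}

#' @export
residuals.orf_dominance <- function(object, ...) {
  if (is.null(object$fit) || is.null(object$fit$model)) {
    stop("no regression fit available")
  }
  stats::residuals(object$fit$model)
}

#' Plot an ORF dominance analysis
#'
#' Left panel: the coding and noncoding relative-frequency histograms
#' over the ten score bins. Right panel: the protein-coding potential
#' F(x) with the fitted line over the bins it used.
#'
#' @param x An `orf_dominance` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.orf_dominance <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  kind <- x$params$score_kind
  graphics::barplot(rbind(f = x$f$freq, g = x$g$freq), beside = TRUE,
                    names.arg = format(x$f$mids), las = 2,
                    col = c("grey20", "grey75"),
                    xlab = paste("ORF", kind), ylab = "relative frequency",
                    legend.text = c("coding f(x)", "noncoding g(x)"), ...)
  graphics::plot(x$potential$mids, x$potential$potential, pch = 19,
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = paste("ORF", kind), ylab = "coding potential F(x)")
  if (!is.null(x$fit)) {
    xs <- seq(0, x$fit$x_max, length.out = 50)
    graphics::lines(xs, predict_potential(x$fit, xs))
  }
  invisible(x)
}
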