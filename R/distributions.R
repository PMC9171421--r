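#' Bin scores into the ten-class relative-frequency histogram
#'
#' Scores in (0, 1] are placed into ten equal-width bins whose medians are
#' 0.05, 0.15, ..., 0.95. Internal bin edges are left-closed (a score of
#' exactly 0.1 goes to the 0.15 bin); 1.0 falls in the last bin.
#'
#' @param scores Numeric vector of scores in (0, 1]; `NA`s are dropped.
#' @param score_kind `"dominance"` (default) or `"coverage"`.
#' @return An object of class `binned_distribution`: a list with elements
#'   `score_kind`, `mids` (the ten bin medians), `counts`, `total`, and
#'   `freq` (relative frequencies; all `NA` when `total` is 0).
#' @export
bin_scores <- function(scores, score_kind = c("dominance", "coverage")) {
  score_kind <- match.arg(score_kind)
  scores <- scores[!is.na(scores)]
  if (any(scores <= 0 | scores > 1)) stop("scores must lie in (0, 1]")
  bin <- findInterval(scores, seq(0.1, 0.9, by = 0.1)) + 1L
  counts <- tabulate(bin, nbins = 10L)
  total <- length(scores)
  structure(list(score_kind = score_kind,
                 mids = seq(0.05, 0.95, by = 0.1),
                 counts = counts,
                 total = total,
                 freq = if (total > 0L) counts / total else
                   rep(NA_real_, 10L)),
            class = "binned_distribution")
}

#' @export
print.binned_distribution <- function(x, ...) {
  cat(sprintf("Binned %s distribution (%d transcripts)\n",
              x$score_kind, x$total))
  print(data.frame(x = x$mids, count = x$counts,
                   freq = round(x$freq, 4)), row.names = FALSE)
  invisible(x)
}

.check_binning <- function(f, g) {
  stopifnot(inherits(f, "binned_distribution"),
            inherits(g, "binned_distribution"))
  if (!identical(f$score_kind, g$score_kind)) {
    stop("distributions have different score kinds: ",
         f$score_kind, " vs ", g$score_kind)
  }
  if (!isTRUE(all.equal(f$mids, g$mids))) stop("binning mismatch")
}

#' Protein-coding potential per dominance bin
#'
#' `F(x) = f(x) / (f(x) + g(x))`, the probability that a transcript with
#' score `x` belongs to the coding class, computed per bin from the
#' coding (`f`) and noncoding (`g`) relative-frequency distributions.
#' Bins where both frequencies are zero are undefined (`NA`).
#'
#' @param f Coding-class [bin_scores()] distribution.
#' @param g Noncoding-class distribution on the same score kind.
#' @return An object of class `coding_potential_table`: list with `mids`,
#'   `potential`, the input frequencies `f`/`g`, and the noncoding bin
#'   counts `g_counts` (used to drop under-populated bins in the fit).
#' @export
coding_potential <- function(f, g) {
  .check_binning(f, g)
  denom <- f$freq + g$freq
  pot <- ifelse(!is.na(denom) & denom > 0, f$freq / denom, NA_real_)
  structure(list(score_kind = f$score_kind, mids = f$mids, potential = pot,
                 f = f$freq, g = g$freq, g_counts = g$counts),
            class = "coding_potential_table")
}

#' @export
print.coding_potential_table <- function(x, ...) {
  cat(sprintf("Protein-coding potential F(x) over %s bins\n", x$score_kind))
  print(data.frame(x = x$mids, f = round(x$f, 4), g = round(x$g, 4),
                   F = round(x$potential, 4)), row.names = FALSE)
  invisible(x)
}

#' Histogram overlap of two binned distributions
#'
#' The overlap score is the sum over bins of the smaller of the two
#' relative frequencies; it is 1 when the distributions are identical and
#' 0 when their supports are disjoint. Computed on dominance it is O_dom,
#' on coverage O_cov.
#'
#' @param f,g [bin_scores()] distributions on the same score kind.
#' @param min_noncoding Minimum transcript count required in `g`
#'   (default 3); fewer is an error, as the overlap of a near-empty
#'   histogram is meaningless.
#' @return Object of class `overlap_result`: list with `score_kind`,
#'   per-bin `o`, and the total `O`.
#' @export
overlap_score <- function(f, g, min_noncoding = 3L) {
  .check_binning(f, g)
  if (f$total < 1L) stop("coding distribution is empty")
  if (g$total < min_noncoding) {
    stop(sprintf("fewer than %d noncoding transcripts (%d)",
                 min_noncoding, g$total))
  }
  o <- pmin(f$freq, g$freq)
  structure(list(score_kind = f$score_kind, o = o, O = sum(o)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Overlap score O_%s = %.4f\n",
              if (x$score_kind == "dominance") "dom" else "cov", x$O))
  invisible(x)
}

#' Construct a linear coding-potential fit from known coefficients
#'
#' Builds a `potential_fit` object directly from a slope and intercept,
#' e.g. to apply a published regression to new dominance values with
#' [predict_potential()].
#'
#' @param slope,intercept Regression coefficients of `F(x) = a x + b`.
#' @param x_max Upper dominance bound of the fit's validity (default 0.65).
#' @param r_squared Optional coefficient of determination.
#' @param bins_used Optional bin medians the fit used.
#' @return An object of class `potential_fit`.
#' @export
potential_fit <- function(slope, intercept, x_max = 0.65,
                          r_squared = NA_real_, bins_used = numeric()) {
  structure(list(slope = slope, intercept = intercept, x_max = x_max,
                 r_squared = r_squared, bins_used = bins_used,
                 model = NULL),
            class = "potential_fit")
}

#' Fit the linear regression of coding potential on score
#'
#' Ordinary least squares of `F(x)` on the bin medians `x`, restricted to
#' bins with `x <= x_max`, a defined potential, and at least
#' `min_bin_count` noncoding transcripts (under-populated bins make F
#' unstable and are dropped, mirroring the treatment of sparse
#' low-dominance lncRNA bins).
#'
#' @param cp A [coding_potential()] table.
#' @param x_max Upper bound on bin medians used (default 0.65).
#' @param min_bin_count Minimum noncoding transcripts per usable bin
#'   (default 5).
#' @param bin_counts Per-bin noncoding counts; defaults to the counts
#'   recorded in `cp`.
#' @return A `potential_fit` with `slope`, `intercept`, `r_squared`,
#'   `x_max`, `bins_used`, and the underlying `lm` fit in `$model`.
#' @export
fit_potential_regression <- function(cp, x_max = 0.65, min_bin_count = 5L,
                                     bin_counts = NULL) {
  stopifnot(inherits(cp, "coding_potential_table"))
  if (is.null(bin_counts)) bin_counts <- cp$g_counts
  usable <- cp$mids <= x_max + 1e-12 & !is.na(cp$potential) &
    bin_counts >= min_bin_count
  if (sum(usable) < 3L) {
    stop("fewer than 3 usable bins for the regression")
  }
  d <- data.frame(x = cp$mids[usable], F = cp$potential[usable])
  m <- stats::lm(F ~ x, data = d)
  ssr <- sum(stats::residuals(m)^2)
  sst <- sum((d$F - mean(d$F))^2)
  structure(list(slope = unname(stats::coef(m)[2L]),
                 intercept = unname(stats::coef(m)[1L]),
                 x_max = x_max,
                 r_squared = if (sst > 0) 1 - ssr / sst else 1,
                 bins_used = d$x,
                 model = m),
            class = "potential_fit")
}

#' @export
print.potential_fit <- function(x, digits = 4, ...) {
  cat(sprintf("F(x) = %s x + %s  (x <= %s)",
              format(x$slope, digits = digits),
              format(x$intercept, digits = digits),
              format(x$x_max)))
  if (!is.na(x$r_squared)) cat(sprintf(", R^2 = %.3f", x$r_squared))
  cat("\n")
  invisible(x)
}

#' @export
coef.potential_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict coding potential from a linear fit
#'
#' Evaluates `slope * x + intercept`, clamped to the probability scale
#' \[0, 1\]. Values of `x` above the fit's `x_max` are extrapolations and
#' trigger a warning.
#'
#' @param fit A `potential_fit`.
#' @param x Dominance (or coverage) values in (0, 1].
#' @return Predicted coding potential, same length as `x`.
#' @examples
#' predict_potential(potential_fit(1.313, 0.0189), 0.568)  # 0.765
#' @export
predict_potential <- function(fit, x) {
  stopifnot(inherits(fit, "potential_fit"), is.numeric(x))
  if (any(x > fit$x_max + 1e-12)) {
    warning(sprintf("predicting above x_max = %s (extrapolation)",
                    format(fit$x_max)))
  }
  pmin(pmax(fit$slope * x + fit$intercept, 0), 1)
}

#' Per-bin frequency of negatively selected transcripts
#'
#' Joins a Ka/Ks table to transcript profiles and computes, per dominance
#' bin, `h(x)`: the fraction of orthologous transcripts in the bin with
#' `Ka/Ks < threshold` (negative, i.e. purifying, selection). Records
#' with `Ka > 1` or `Ks > 1` are excluded first as outliers; records with
#' `Ks = 0` have an undefined ratio and are dropped with a warning.
#'
#' @param kaks Data frame with columns `transcript_id`, `ka`, `ks`.
#' @param profiles Profile data frame with defined dominance.
#' @param threshold Ka/Ks cutoff for negative selection (default 0.5).
#' @return Object of class `negative_selection_table`: a data frame with
#'   per-bin `x`, `n_orthologous`, `n_negative`, and `h` (`NA` where no
#'   transcript falls in the bin).
#' @export
negative_selection_frequency <- function(kaks, profiles, threshold = 0.5) {
  stopifnot(all(c("transcript_id", "ka", "ks") %in% names(kaks)))
  if (any(kaks$ka < 0 | kaks$ks < 0, na.rm = TRUE)) {
    stop("ka and ks must be nonnegative")
  }
  kaks <- kaks[!(kaks$ka > 1 | kaks$ks > 1), , drop = FALSE]
  if (any(kaks$ks == 0)) {
    warning(sum(kaks$ks == 0), " record(s) with Ks = 0 dropped (ratio undefined)")
    kaks <- kaks[kaks$ks > 0, , drop = FALSE]
  }
  m <- merge(kaks, profiles[, c("transcript_id", "dominance")],
             by = "transcript_id")
  m <- m[!is.na(m$dominance), , drop = FALSE]
  mids <- seq(0.05, 0.95, by = 0.1)
  if (!nrow(m)) {
    tab <- data.frame(x = mids, n_orthologous = 0L, n_negative = 0L,
                      h = NA_real_)
    return(structure(tab, class = c("negative_selection_table",
                                    "data.frame")))
  }
  bin <- findInterval(m$dominance, seq(0.1, 0.9, by = 0.1)) + 1L
  n_or <- tabulate(bin, nbins = 10L)
  neg <- (m$ka / m$ks) < threshold
  n_ns <- tabulate(bin[neg], nbins = 10L)
  tab <- data.frame(x = mids, n_orthologous = n_or, n_negative = n_ns,
                    h = ifelse(n_or > 0L, n_ns / n_or, NA_real_))
  structure(tab, class = c("negative_selection_table", "data.frame"))
}

#' Stratify dominance distributions by group
#'
#' Splits the profiles by an arbitrary grouping of transcript ids (e.g.
#' the number of tissues a transcript is detected in) and bins each
#' group's dominance scores separately.
#'
#' @param profiles Profile data frame.
#' @param groups Either a named character/factor vector (names are
#'   transcript ids) or a data frame with columns `transcript_id` and
#'   `group`.
#' @return Named list of [bin_scores()] distributions, one per group.
#' @export
stratify_distributions <- function(profiles, groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("transcript_id", "group") %in% names(groups)))
    ids <- groups$transcript_id
    key <- as.character(groups$group)
  } else {
    ids <- names(groups)
    key <- as.character(groups)
    if (is.null(ids)) stop("'groups' must be named by transcript id")
  }
  unknown <- setdiff(ids, profiles$transcript_id)
  if (length(unknown)) {
    stop("unknown transcript id(s): ",
         paste(utils::head(unknown, 10L), collapse = ", "))
  }
  dom <- profiles$dominance[match(ids, profiles$transcript_id)]
  lapply(split(dom, key), bin_scores)
}
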