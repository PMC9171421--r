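test_that("binning follows the ten-class edge rules", {
  b <- bin_scores(c(1.0, 1.0))
  expect_equal(b$counts[10], 2L)
  expect_equal(b$freq[10], 1)
  expect_equal(sum(b$counts[-10]), 0L)
  # the NCYM dominance falls in the class with median 0.55
  expect_equal(bin_scores(0.568)$mids[bin_scores(0.568)$counts == 1L], 0.55)
  # internal edges go to the higher bin
  expect_equal(which(bin_scores(0.1)$counts == 1L), 2L)
  expect_equal(which(bin_scores(0.9)$counts == 1L), 10L)
  expect_error(bin_scores(c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(bin_scores(0), "\\(0, 1\\]")
  empty <- bin_scores(numeric())
  expect_equal(empty$total, 0L)
  expect_true(all(is.na(empty$freq)))
})

test_that("bin counts match a direct tally and frequencies normalize", {
  set.seed(123)
  for (i in 1:5) {
    x <- runif(1000)
    x[x == 0] <- 0.5
    b <- bin_scores(x)
    expect_equal(b$counts, oracle_bin_counts(x))
    expect_equal(sum(b$freq), 1, tolerance = 1e-9)
  }
})

test_that("coding potential reproduces the worked bin example", {
  # construct distributions whose 0.15-bin frequencies are 0.060 and 0.268
  f <- bin_scores(c(rep(0.55, 940), rep(0.15, 60)))
  g <- bin_scores(c(rep(0.55, 732), rep(0.15, 268)))
  cp <- coding_potential(f, g)
  expect_equal(cp$f[2], 0.060)
  expect_equal(cp$g[2], 0.268)
  expect_equal(round(cp$potential[2], 3), 0.183)
  expect_equal(cp$potential[2], 0.060 / (0.060 + 0.268))
})

test_that("coding potential handles pure and symmetric bins", {
  f <- bin_scores(c(rep(0.15, 2), rep(0.35, 2), rep(0.55, 6)))
  g <- bin_scores(c(rep(0.15, 2), rep(0.25, 8)))
  cp <- coding_potential(f, g)
  expect_equal(cp$potential[6], 1)            # g = 0 there
  expect_equal(cp$potential[2], 0.5)          # f = g = 0.2
  expect_true(all(is.na(cp$potential[7:10]))) # both zero
  pot <- cp$potential[!is.na(cp$potential)]
  expect_true(all(pot >= 0 & pot <= 1))
  cov <- bin_scores(0.5, "coverage")
  expect_error(coding_potential(f, cov), "score kind")
})

test_that("overlap score obeys its bounds, symmetry, and guards", {
  f <- bin_scores(c(rep(0.15, 5), rep(0.35, 5)))
  g <- bin_scores(c(rep(0.35, 5), rep(0.55, 5)))
  expect_equal(overlap_score(f, g)$O, 0.5)
  expect_equal(overlap_score(f, f)$O, 1)
  disjoint <- bin_scores(rep(0.95, 5))
  expect_equal(overlap_score(f, disjoint)$O, 0)
  expect_equal(overlap_score(f, g)$O, overlap_score(g, f, min_noncoding = 1)$O)
  expect_error(overlap_score(f, bin_scores(c(0.5, 0.5))),
               "fewer than 3 noncoding")
  expect_error(overlap_score(bin_scores(numeric()), f), "empty")
  set.seed(5)
  for (i in 1:20) {
    a <- bin_scores(runif(50, min = .Machine$double.eps))
    b <- bin_scores(runif(50, min = .Machine$double.eps))
    O <- overlap_score(a, b)$O
    expect_true(O >= 0 && O <= 1 + 1e-12)
  }
})

test_that("the F(x) regression recovers known coefficients", {
  mids <- seq(0.05, 0.95, by = 0.1)
  make_cp <- function(pot, g_counts = rep(100L, 10L)) {
    structure(list(score_kind = "dominance", mids = mids, potential = pot,
                   f = rep(0.1, 10), g = rep(0.1, 10), g_counts = g_counts),
              class = "coding_potential_table")
  }
  # exactly linear over the usable range
  fit <- fit_potential_regression(make_cp(1.25 * mids + 0.03))
  expect_equal(fit$slope, 1.25, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.03, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$bins_used, mids[mids < 0.651])
  # constant potential: zero slope
  flat <- fit_potential_regression(make_cp(rep(0.4, 10)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$intercept, 0.4, tolerance = 1e-12)
  # under-populated and undefined bins are dropped
  pot <- 1.25 * mids + 0.03
  pot[3] <- NA
  fit2 <- fit_potential_regression(make_cp(pot, g_counts = c(2L, rep(100L, 9L))))
  expect_equal(fit2$bins_used, mids[c(2, 4:7)])
  expect_error(fit_potential_regression(make_cp(c(0.1, 0.2, rep(NA, 8)))),
               "fewer than 3")
})

test_that("noisy regression matches closed-form normal equations", {
  mids <- seq(0.05, 0.95, by = 0.1)
  set.seed(2024)
  for (i in 1:20) {
    pot <- 1.3 * mids + 0.02 + rnorm(10, sd = 0.01)
    cp <- structure(list(score_kind = "dominance", mids = mids,
                         potential = pot, f = rep(0.1, 10), g = rep(0.1, 10),
                         g_counts = rep(50L, 10L)),
                    class = "coding_potential_table")
    fit <- fit_potential_regression(cp)
    want <- oracle_ols(mids[mids < 0.651], pot[mids < 0.651])
    expect_equal(fit$slope, want$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, want$intercept, tolerance = 1e-9)
    expect_equal(fit$r_squared, want$r_squared, tolerance = 1e-9)
    expect_true(abs(fit$slope - 1.3) < 0.1)
  }
})

test_that("prediction applies the published human fits and clamps", {
  expect_equal(round(predict_potential(potential_fit(1.313, 0.0189), 0.568), 3),
               0.765)
  expect_equal(round(predict_potential(potential_fit(1.301, 0.0072), 0.568), 3),
               0.746)
  f <- potential_fit(1.5, 0.1)
  expect_equal(predict_potential(f, 0), 0.1)
  expect_warning(p <- predict_potential(f, 0.9), "extrapolation")
  expect_equal(p, 1)  # clamped to the probability scale
  expect_equal(coef(f), c(intercept = 0.1, slope = 1.5))
})

test_that("negative-selection frequency applies outlier and ratio rules", {
  prof <- data.frame(transcript_id = sprintf("t%03d", 1:200),
                     dominance = rep(seq(0.05, 0.95, by = 0.1), 20))
  # all under threshold -> h = 1 everywhere occupied
  k1 <- data.frame(transcript_id = prof$transcript_id, ka = 0.1, ks = 0.9)
  h1 <- negative_selection_frequency(k1, prof)
  expect_true(all(h1$h[h1$n_orthologous > 0] == 1))
  # none under threshold -> h = 0
  k0 <- data.frame(transcript_id = prof$transcript_id, ka = 0.9, ks = 0.95)
  h0 <- negative_selection_frequency(k0, prof)
  expect_true(all(h0$h[h0$n_orthologous > 0] == 0))
  # seeded mixture against a direct tally
  set.seed(31)
  kk <- data.frame(transcript_id = prof$transcript_id,
                   ka = runif(200, 0, 1.3), ks = runif(200, 0, 1.3))
  expect_warning(
    h <- negative_selection_frequency(rbind(kk,
      data.frame(transcript_id = "zz", ka = 0.1, ks = 0)), prof),
    "Ks = 0")
  keep <- kk$ka <= 1 & kk$ks <= 1 & kk$ks > 0
  dd <- merge(kk[keep, ], prof, by = "transcript_id")
  bin <- floor(pmin(dd$dominance, 1 - 1e-12) * 10) + 1
  for (b in 1:10) {
    inbin <- bin == b
    if (!any(inbin)) next
    expect_equal(h$h[b], mean(dd$ka[inbin] / dd$ks[inbin] < 0.5))
  }
  # order invariance
  perm <- sample(nrow(kk))
  expect_equal(negative_selection_frequency(kk, prof),
               negative_selection_frequency(kk[perm, ], prof))
})

test_that("stratified distributions partition the transcript set", {
  prof <- data.frame(transcript_id = sprintf("t%03d", 1:90),
                     dominance = runif(90, min = 1e-6))
  all_one <- stratify_distributions(prof,
    setNames(rep("g", 90), prof$transcript_id))
  expect_equal(all_one$g$counts, bin_scores(prof$dominance)$counts)
  set.seed(8)
  grp <- setNames(sample(c("a", "b", "c"), 90, replace = TRUE),
                  prof$transcript_id)
  strat <- stratify_distributions(prof, grp)
  expect_equal(sum(vapply(strat, `[[`, integer(1), "total")), 90L)
  for (k in names(strat)) {
    expect_equal(strat[[k]]$counts,
                 oracle_bin_counts(prof$dominance[grp == k]))
  }
  expect_error(stratify_distributions(prof, c(nope = "a")),
               "unknown transcript id")
})
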