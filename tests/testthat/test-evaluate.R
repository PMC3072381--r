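# ROC/AUC, classifier operating points, contingency statistics, trend
# test, and track correlations.

test_that("roc_auc handles perfect, inverted, and tied predictors", {
  expect_equal(roc_auc(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(c(3, 2, 1, 0), c(FALSE, FALSE, TRUE, TRUE))$auc, 0)
  expect_equal(roc_auc(c(1, 1, 0), c(TRUE, FALSE, FALSE))$auc, 0.75)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "single class")
})

test_that("roc_auc equals the pairwise brute-force oracle", {
  set.seed(21)
  for (rep_i in 1:8) {
    n <- sample(20:200, 1)
    scores <- sample(0:12, n, replace = TRUE) # heavy ties, like GC counts
    labels <- runif(n) < plogis((scores - 6) / 2)
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, oracle_auc(scores, labels))
    # the trapezoid area of the reported curve equals the rank AUC
    expect_equal(trapezoid_area(r$points), r$auc)
    # complement identity
    expect_equal(roc_auc(scores, !labels)$auc, 1 - r$auc)
  }
})

test_that("roc curve is monotone from (0,0) to (1,1)", {
  set.seed(22)
  r <- roc_auc(rnorm(500), runif(500) < 0.3)
  pts <- r$points
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("binary_predictor_point computes sensitivity/specificity", {
  l <- rep(c(TRUE, FALSE), c(10, 10))
  expect_equal(unname(binary_predictor_point(l, l)), c(1, 1))
  expect_equal(unname(binary_predictor_point(rep(TRUE, 20), l)), c(1, 0))
  p <- c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 4), rep(FALSE, 6))
  expect_equal(unname(binary_predictor_point(p, l)), c(0.8, 0.6))
  expect_error(binary_predictor_point(l, rep(TRUE, 20)), "single class")
})

test_that("methylation_overlap_stats counts overlaps and derives rates", {
  fx <- contingency_fixture(30, 10, 5, 15)
  st <- methylation_overlap_stats(fx$islands, fx$regions)
  expect_equal(unname(st$table["unmethylated", "retained"]), 30L)
  expect_equal(st$precision, 30 / 35)
  expect_equal(st$recall, 30 / 40)
  # precision/recall always recompute from the emitted table
  expect_equal(st$precision,
               st$table[1, 1] / sum(st$table[, 1]))
  expect_equal(st$recall, st$table[1, 1] / sum(st$table[1, ]))

  # regions covering everything: recall 1, precision = base rate
  all_reg <- GenomicRanges::reduce(fx$islands)
  st2 <- methylation_overlap_stats(fx$islands, all_reg)
  expect_equal(st2$recall, 1)
  expect_equal(st2$precision, 40 / 60)

  # no overlap at all -> precision undefined
  far <- gr("chrOther", 0, 100)
  expect_error(methylation_overlap_stats(fx$islands, far), "undefined")
  expect_error(methylation_overlap_stats(fx$islands[0], far), "empty")
})

test_that("cochran_armitage_trend matches stats::prop.trend.test", {
  set.seed(23)
  for (i in 1:6) {
    k <- sample(3:11, 1)
    tot <- sample(50:500, k)
    p <- plogis(seq(-1, 1, length.out = k) + rnorm(1))
    suc <- rbinom(k, tot, p)
    sc <- sort(sample(0:50, k))
    got <- cochran_armitage_trend(tot, suc, sc)
    ref <- stats::prop.trend.test(suc, tot, score = sc)
    expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("cochran_armitage_trend is affine-invariant and degenerates to 0", {
  tot <- c(100L, 100L)
  expect_equal(cochran_armitage_trend(tot, c(10L, 10L))$chi2, 0)
  got <- cochran_armitage_trend(c(100, 100), c(10, 20), c(0, 1))
  got2 <- cochran_armitage_trend(c(100, 100), c(10, 20), c(7, 7 + 3))
  expect_equal(got$chi2, got2$chi2, tolerance = 1e-12)
  # all successes -> variance 0 -> chi2 0, p 1
  d <- cochran_armitage_trend(c(10, 10), c(10, 10))
  expect_equal(d$chi2, 0)
  expect_equal(d$p, 1)
  expect_error(cochran_armitage_trend(c(10, 10), c(11, 0)), "0..total")
})

test_that("chisq_independence matches the 2x2 closed form", {
  m <- matrix(c(50, 0, 0, 50), 2)
  got <- chisq_independence(m)
  expect_equal(got$chi2, 100)
  # closed form n(ad-bc)^2 / product of margins, cross-checked with
  # stats::chisq.test
  set.seed(24)
  for (i in 1:5) {
    t2 <- matrix(rpois(4, 40) + 1L, 2)
    g <- chisq_independence(t2)
    ref <- suppressWarnings(stats::chisq.test(t2, correct = FALSE))
    expect_equal(g$chi2, unname(ref$statistic), tolerance = 1e-12)
    # row swap symmetry
    expect_equal(chisq_independence(t2[2:1, ])$chi2, g$chi2)
  }
  # perfectly proportional table
  expect_equal(chisq_independence(matrix(c(10, 20, 30, 60), 2))$chi2, 0)
  expect_error(chisq_independence(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("window_track_correlation recovers known correlations", {
  x <- rnorm(100)
  expect_equal(window_track_correlation(x, x), 1)
  expect_equal(window_track_correlation(x, -x), -1)
  set.seed(25)
  n <- 10000
  a <- rnorm(n)
  b <- 0.7 * a + sqrt(1 - 0.49) * rnorm(n)
  expect_lt(abs(window_track_correlation(a, b) - 0.7), 0.02)
  # mask drops excluded windows
  a2 <- c(a, 1e6)
  b2 <- c(b, -1e6)
  mask <- c(rep(TRUE, n), FALSE)
  expect_equal(window_track_correlation(a2, b2, mask = mask),
               window_track_correlation(a, b))
})

test_that("stratified correlation skips sparse strata and bounds r", {
  set.seed(26)
  g <- rep(c(1L, 2L, 3L), c(500, 500, 2))
  a <- rnorm(1002)
  b <- a + rnorm(1002)
  res <- window_track_correlation(a, b, stratify_by = g)
  expect_equal(nrow(res), 3L)
  expect_true(res$skipped[res$stratum == 3])
  done <- res[!res$skipped, ]
  expect_true(all(done$ci_lo <= done$r & done$r <= done$ci_hi))
})
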