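# Read shifting, center counting, subsampling, retention scores, and
# the enrichment-region caller.

test_that("shift_read_to_center follows the direction of sequencing", {
  r <- reads_df("chr1", c(1000, 1000, 30), c("+", "-", "-"))
  expect_equal(shift_read_to_center(r, 75), c(1075L, 925L, -45L))
  # the negative center is excluded at counting time
  grid <- window_grid(c(chr1 = 1500L), 150L)
  cnt <- count_positions_in_windows(r$chrom, shift_read_to_center(r, 75), grid)
  expect_equal(sum(cnt), 2L)
})

test_that("center counting uses half-open windows and conserves totals", {
  grid <- window_grid(c(chr1 = 450L), 150L)
  cnt <- count_positions_in_windows(rep("chr1", 3), c(10L, 149L, 160L), grid)
  expect_equal(cnt, c(2L, 1L, 0L))
  expect_equal(count_positions_in_windows("chr1", 150L, grid),
               c(0L, 1L, 0L))

  set.seed(1)
  pos <- sample(0L:449L, 1000, replace = TRUE)
  expect_equal(sum(count_positions_in_windows(rep("chr1", 1000), pos, grid)),
               1000L)
  expect_warning(count_positions_in_windows("chrNope", 5L, grid), "skipped")
})

test_that("dedup collapses identical records before shifting", {
  r <- reads_df(c("chr1", "chr1", "chr1", "chr1"),
                c(10, 10, 200, 400), c("+", "+", "-", "+"))
  expect_equal(nrow(dedup_reads(r)), 3L)
  grid <- window_grid(c(chr1 = 600L), 150L)
  expect_equal(sum(center_counts(r, grid, shift_bp = 75, dedup = TRUE)), 3L)
  expect_equal(sum(center_counts(r, grid, shift_bp = 75, dedup = FALSE)), 4L)
})

test_that("subsample_reads is exact, deterministic, and validated", {
  r <- reads_df(rep("chr1", 100), 0:99, rep("+", 100))
  expect_identical(subsample_reads(r, 100, seed = 9), r)
  a <- subsample_reads(r, 40, seed = 9)
  b <- subsample_reads(r, 40, seed = 9)
  expect_identical(a, b)
  expect_equal(nrow(a), 40L)
  expect_false(identical(a, subsample_reads(r, 40, seed = 10)))
  expect_error(subsample_reads(r, 101, seed = 1), "exceeds")
  # caller's RNG stream is untouched
  set.seed(123)
  x1 <- runif(1)
  set.seed(123)
  invisible(subsample_reads(r, 10, seed = 5))
  expect_equal(runif(1), x1)
})

test_that("subsampling matches the hypergeometric mean per window", {
  # 4 windows with known counts; mean retained count over seeds must
  # approach count * target/total
  grid <- window_grid(c(chr1 = 600L), 150L)
  counts <- c(40L, 100L, 20L, 40L)
  pos <- rep(window_starts(grid) + 75L, counts)
  r <- reads_df(rep("chr1", sum(counts)), pos, rep("+", sum(counts)))
  target <- 100L
  sims <- vapply(1:200, function(s) {
    sub <- subsample_reads(r, target, seed = s)
    count_positions_in_windows(sub$chrom, sub$pos, grid)
  }, numeric(4))
  m <- rowMeans(sims)
  expected <- counts * target / sum(counts)
  se <- sqrt(counts * (target / sum(counts)) *
             (1 - target / sum(counts))) / sqrt(200)
  expect_true(all(abs(m - expected) < 4 * pmax(se, 0.05)))
})

test_that("normalized_retention_score matches its closed form", {
  expect_equal(normalized_retention_score(7, 7), 0)
  expect_equal(normalized_retention_score(9, 4), 5 / sqrt(13))
  expect_equal(normalized_retention_score(0, 9), -3)
  expect_error(normalized_retention_score(0, 0), "undefined")
  expect_error(normalized_retention_score(-1, 2), "non-negative")
  # antisymmetry S(n, i) = -S(i, n)
  set.seed(2)
  n <- rpois(50, 10)
  i <- rpois(50, 10)
  ok <- n + i > 0
  expect_equal(normalized_retention_score(n[ok], i[ok]),
               -normalized_retention_score(i[ok], n[ok]))
})

test_that("low_coverage_filter applies the >= 5 total-read rule", {
  expect_false(low_coverage_filter(3, 1))
  expect_true(low_coverage_filter(3, 2))
  expect_true(low_coverage_filter(0, 5))
})

test_that("retention_score_track combines scores with exclusion flags", {
  tr <- retention_score_track(c(9L, 0L, 3L), c(4L, 0L, 1L),
                              min_total = 5L,
                              excluded = c(FALSE, FALSE, TRUE))
  expect_equal(tr$score[1], 5 / sqrt(13))
  expect_true(is.na(tr$score[2]))
  expect_equal(tr$keep, c(TRUE, FALSE, FALSE))
})

test_that("binomial_enrichment_score is an upper-tail -log10", {
  expect_equal(binomial_enrichment_score(0, 10, 0.5), 0)
  expect_equal(binomial_enrichment_score(8, 2, 0.5),
               -log10(sum(dbinom(8:10, 10, 0.5))), tolerance = 1e-12)
  # near zero at the expectation
  expect_lt(binomial_enrichment_score(50, 50, 0.5), 0.6)
  expect_error(binomial_enrichment_score(1, 1, 1.2), "depth_ratio")
  # deep enrichment stays finite via log-scale computation
  expect_true(is.finite(binomial_enrichment_score(5000, 100, 0.5)))
})

test_that("call_enriched_regions finds planted hotspots and nothing else", {
  sl <- c(chr1 = 30000L)
  set.seed(31)
  # uniform input; nucleosome reads concentrated in [9000, 9300)
  inp <- reads_df(rep("chr1", 2000),
                  sample(100L:29800L, 2000, replace = TRUE),
                  sample(c("+", "-"), 2000, replace = TRUE))
  hot_centers <- sample(9000L:9299L, 400, replace = TRUE)
  str <- sample(c("+", "-"), 400, replace = TRUE)
  nuc <- reads_df(rep("chr1", 400),
                  ifelse(str == "+", hot_centers - 75L, hot_centers + 75L),
                  str)
  reg <- call_enriched_regions(nuc, inp, sl)
  expect_equal(length(reg), 1L)
  expect_true(GenomicRanges::start(reg) <= 9001 &&
              GenomicRanges::end(reg) >= 9300)
  expect_true(reg$enrichment_score > 2)

  # null: identical read sets give no regions
  expect_equal(length(call_enriched_regions(inp, inp, sl)), 0L)

  # one-sidedness: swapping labels never reproduces the forward calls
  swapped <- call_enriched_regions(inp, nuc, sl)
  expect_false(identical(as.data.frame(GenomicRanges::ranges(swapped)),
                         as.data.frame(GenomicRanges::ranges(reg))))
  # the hotspot itself is never "input-enriched"
  if (length(swapped) > 0)
    expect_equal(
      length(GenomicRanges::findOverlaps(gr("chr1", 9000, 9300), swapped,
                                         type = "within")), 0L)
})

test_that("two separated hotspots give two disjoint regions", {
  sl <- c(chr1 = 30000L)
  set.seed(32)
  inp <- reads_df(rep("chr1", 2000),
                  sample(100L:29800L, 2000, replace = TRUE),
                  sample(c("+", "-"), 2000, replace = TRUE))
  mk_hot <- function(lo, hi, n) {
    cc <- sample(lo:hi, n, replace = TRUE)
    st <- sample(c("+", "-"), n, replace = TRUE)
    reads_df(rep("chr1", n), ifelse(st == "+", cc - 75L, cc + 75L), st)
  }
  nuc <- rbind(mk_hot(6000L, 6299L, 300), mk_hot(20000L, 20299L, 300))
  reg <- call_enriched_regions(nuc, inp, sl)
  expect_equal(length(reg), 2L)
  expect_true(GenomicRanges::start(reg)[2] > GenomicRanges::end(reg)[1])
})

test_that("retention_params validates its constants", {
  p <- retention_params()
  expect_equal(p$shift_bp, 75L)
  expect_equal(p$window_bp, 150L)
  expect_equal(p$min_total_reads, 5L)
  expect_equal(p$caller_window_bp, 300L)
  expect_error(retention_params(shift_bp = -1), "positive")
  expect_error(retention_params(caller_window_bp = 250, caller_step_bp = 150),
               "multiple")
})
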