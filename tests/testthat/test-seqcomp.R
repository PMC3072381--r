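# Window grids, base-composition tracks, k-mer uniqueness, CpG islands.

test_that("make_windows tiles chromosomes and drops trailing partials", {
  g <- make_genome(chrA = strrep("A", 450))
  grid <- make_windows(g, 150)
  expect_equal(grid$n, 3L)
  expect_equal(window_starts(grid), c(0L, 150L, 300L))

  g2 <- make_genome(chrA = strrep("A", 449))
  expect_equal(make_windows(g2, 150)$n, 2L)

  g3 <- make_genome(chr1 = strrep("A", 300), chr2 = strrep("C", 300))
  grid3 <- make_windows(g3, 150)
  expect_equal(grid3$n, 4L)
  expect_equal(window_chroms(grid3), c("chr1", "chr1", "chr2", "chr2"))
  expect_equal(window_starts(grid3), c(0L, 150L, 0L, 150L))

  expect_error(make_windows(g, 0), "positive")
  expect_error(make_windows(g, -5), "positive")
})

test_that("window_index maps positions with half-open windows", {
  grid <- window_grid(c(chr1 = 450L), 150L)
  expect_equal(window_index(grid, "chr1", c(0L, 149L, 150L, 449L)),
               c(1L, 1L, 2L, 3L))
  expect_true(is.na(window_index(grid, "chr1", -1L)))
  expect_true(is.na(window_index(grid, "chrX", 10L)))
  # position in the dropped trailing partial window
  grid2 <- window_grid(c(chr1 = 449L), 150L)
  expect_true(is.na(window_index(grid2, "chr1", 448L)))
})

test_that("window_base_counts counts GC, within-window CpG, and N", {
  w <- 10L
  g <- make_genome(chrA = paste0(strrep("GC", 5),   # all G/C
                                 "ACGTACGTAC",      # gc 5, cpg 2
                                 "ACGNNTACGT"))     # contains N
  grid <- make_windows(g, w)
  comp <- window_base_counts(g, grid)
  expect_equal(comp$gc[1], w)
  expect_equal(comp$gc[2], 5L)
  expect_equal(comp$cpg[2], 2L)
  expect_equal(comp$n[3], 2L)
  expect_true(comp$n[3] >= 1L) # flagged for downstream exclusion

  # a CG straddling a window boundary is counted in neither window
  g2 <- make_genome(chrA = paste0(strrep("A", 9), "CG", strrep("A", 9)))
  comp2 <- window_base_counts(g2, make_windows(g2, 10))
  expect_equal(comp2$cpg, c(0L, 0L))
  expect_equal(comp2$gc, c(1L, 1L))
})

test_that("composition counts satisfy conservation and bounds", {
  g <- random_genome(c(chr1 = 1501, chr2 = 997), seed = 7, gc = 0.45)
  grid <- make_windows(g, 150)
  comp <- window_base_counts(g, grid)
  for (ch in c("chr1", "chr2")) {
    nw <- grid$nwin[[ch]]
    pre <- Biostrings::subseq(g[[ch]], 1, nw * 150)
    lf <- Biostrings::letterFrequency(pre, c("G", "C"))
    sel <- window_chroms(grid) == ch
    expect_equal(sum(comp$gc[sel]), unname(sum(lf)))
  }
  # cpg <= min(#C, #G) per window
  v <- Biostrings::Views(g[["chr1"]], start = seq(1, by = 150,
                                      length.out = grid$nwin[["chr1"]]),
             width = 150)
  lf <- Biostrings::letterFrequency(v, c("C", "G"))
  sel <- window_chroms(grid) == "chr1"
  expect_true(all(comp$cpg[sel] <= pmin(lf[, "C"], lf[, "G"])))
  expect_true(all(comp$gc + comp$n <= 150L))
})

test_that("kmer_uniqueness_mask handles degenerate genomes", {
  g <- make_genome(chrA = strrep("A", 100))
  grid <- make_windows(g, 25)
  expect_true(all(!kmer_uniqueness_mask(g, grid, k = 20)))

  dup <- random_genome(c(chr1 = 300), seed = 3)
  g2 <- Biostrings::DNAStringSet(c(chr1 = as.character(dup[[1]]),
                       chr2 = as.character(dup[[1]])))
  expect_true(all(!kmer_uniqueness_mask(g2, make_windows(g2, 50), k = 20)))

  expect_error(kmer_uniqueness_mask(g, grid, k = 0), "k must be")
  expect_error(kmer_uniqueness_mask(g, grid, k = 26), "k must be")
})

test_that("kmer_uniqueness_mask matches the brute-force oracle", {
  for (seed in c(11, 12)) {
    g <- random_genome(c(chr1 = 700, chr2 = 420), seed = seed, gc = 0.5)
    # plant a repeat across chromosomes so both outcomes occur
    s1 <- as.character(g[[1]])
    s2 <- as.character(g[[2]])
    substr(s2, 101, 130) <- substr(s1, 201, 230)
    g <- Biostrings::DNAStringSet(c(chr1 = s1, chr2 = s2))
    grid <- make_windows(g, 70)
    got <- kmer_uniqueness_mask(g, grid, k = 20)
    expect_equal(got, oracle_kmer_unique(g, 70, 20))
    expect_false(all(got))
    expect_true(any(got))
  }
})

test_that("detect_cpg_islands applies the classical thresholds", {
  at <- strrep("AT", 500)
  g <- make_genome(chrA = paste0(at, strrep("CG", 125), at))
  isl <- detect_cpg_islands(g)
  expect_equal(length(isl), 1L)
  # exactly one island covering the planted 250-bp CG repeat (qualifying
  # seeds may legitimately pull in up to ~100 bp of AT margin)
  expect_true(GenomicRanges::start(isl) <= 1001 &&
              GenomicRanges::end(isl) >= 1250)
  expect_gte(GenomicRanges::width(isl), 200L)
  expect_gte(isl$gc_fraction, 0.5)
  expect_gte(isl$obs_exp_cpg, 0.6)

  expect_equal(length(detect_cpg_islands(make_genome(chrA = strrep("AT", 400)))),
               0L)

  # a 199-bp perfect-CpG sequence is shorter than min_len = 200
  g3 <- make_genome(chrA = substr(strrep("CG", 100), 1, 199))
  expect_equal(length(detect_cpg_islands(g3, min_len = 200)), 0L)
})

test_that("detected islands are disjoint and satisfy thresholds on recount", {
  g <- random_genome(c(chr1 = 20000), seed = 5, gc = 0.55)
  isl <- detect_cpg_islands(g, min_len = 200, min_gc = 0.5, min_oe = 0.6)
  if (length(isl) > 1)
    expect_true(all(GenomicRanges::width(GenomicRanges::reduce(isl)) ==
                    GenomicRanges::width(isl)))
  for (i in seq_along(isl)) {
    s <- Biostrings::subseq(g[[1]], GenomicRanges::start(isl)[i],
                GenomicRanges::end(isl)[i])
    L <- length(s)
    nC <- Biostrings::letterFrequency(s, "C")
    nG <- Biostrings::letterFrequency(s, "G")
    nCG <- Biostrings::countPattern("CG", s)
    expect_gte((nC + nG) / L, 0.5)
    expect_gte(nCG * L / (nC * nG), 0.6)
    expect_gte(L, 200)
  }
})
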