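# Nucleosome retention scoring: 5'-end read records -> fragment-center
# window counts -> normalized retention scores; enrichment-region calling
# against the genomic input control; binomial scores for modified
# nucleosomes.
#
# Reads are plain data frames with columns chrom (character),
# pos (0-based 5' end) and strand ("+"/"-"); see read_reads_tsv()/
# read_reads_bed() for the on-disk formats.

#' Default parameters of the retention workflow
#'
#' @param shift_bp Read 5'-end shift towards the fragment center (half the
#'   mononucleosome fragment length; default 75).
#' @param window_bp Scoring window width (default 150).
#' @param min_total_reads Minimum nucleosome + input reads per window
#'   (default 5); windows below are excluded from scoring/ROC.
#' @param caller_window_bp Sliding-window width of the region caller
#'   (default 300).
#' @param caller_step_bp Caller step (default 150, half-window).
#' @param caller_alpha Benjamini-Hochberg FDR threshold (default 0.05).
#' @param subsample_seed Seed used when the nucleosome library is
#'   subsampled to input depth.
#' @return A `retention_params` list.
#' @export
retention_params <- function(shift_bp = 75L, window_bp = 150L,
                             min_total_reads = 5L, caller_window_bp = 300L,
                             caller_step_bp = 150L, caller_alpha = 0.05,
                             subsample_seed = 1L) {
  p <- list(shift_bp = as.integer(shift_bp), window_bp = as.integer(window_bp),
            min_total_reads = as.integer(min_total_reads),
            caller_window_bp = as.integer(caller_window_bp),
            caller_step_bp = as.integer(caller_step_bp),
            caller_alpha = caller_alpha,
            subsample_seed = as.integer(subsample_seed))
  if (any(vapply(p, function(x) length(x) != 1L || is.na(x) || x <= 0, TRUE)))
    stop("all retention parameters must be positive scalars")
  if (p$caller_window_bp %% p$caller_step_bp != 0L)
    stop("caller window must be a multiple of the caller step")
  structure(p, class = "retention_params")
}

.check_reads <- function(reads) {
  if (!is.data.frame(reads) ||
      !all(c("chrom", "pos", "strand") %in% names(reads)))
    stop("reads must be a data.frame with columns chrom, pos, strand")
  if (!all(reads$strand %in% c("+", "-")))
    stop("read strand must be '+' or '-'")
  invisible(reads)
}

#' Shift 5'-end read positions to fragment centers
#'
#' Plus-strand reads move right, minus-strand reads move left, by
#' `shift_bp` ("in the direction of sequencing").  Centers falling outside
#' the chromosome are dropped by the counting step, not here.
#'
#' @param reads Read data.frame (chrom, pos, strand).
#' @param shift_bp Shift in bp (default 75).
#' @return Integer vector of 0-based center positions, aligned to `reads`.
#' @export
shift_read_to_center <- function(reads, shift_bp = 75L) {
  .check_reads(reads)
  as.integer(reads$pos + ifelse(reads$strand == "+", shift_bp, -shift_bp))
}

#' Collapse identical read records
#'
#' Removes duplicate (chrom, pos, strand) records, keeping one copy each.
#'
#' @param reads Read data.frame.
#' @return De-duplicated data.frame.
#' @export
dedup_reads <- function(reads) {
  .check_reads(reads)
  reads[!duplicated(reads[c("chrom", "pos", "strand")]), , drop = FALSE]
}

#' Count positions in grid windows
#'
#' Half-open window convention: a position p falls in the window with
#' start <= p < start + width.  Positions on unknown chromosomes or in
#' the dropped trailing partial window are skipped (with a warning for
#' unknown chromosomes).
#'
#' @param chrom,pos Character/integer vectors of 0-based positions.
#' @param grid A [window_grid()].
#' @return Integer vector of counts aligned to the grid.
#' @export
count_positions_in_windows <- function(chrom, pos, grid) {
  stopifnot(inherits(grid, "window_grid"))
  unknown <- !(chrom %in% names(grid$seqlengths))
  if (any(unknown))
    warning(sum(unknown), " record(s) on chromosomes absent from the grid; skipped")
  idx <- window_index(grid, chrom, pos)
  tabulate(idx[!is.na(idx)], nbins = grid$n)
}

#' Fragment-center counts per window from 5'-end reads
#'
#' @param reads Read data.frame (chrom, pos, strand).
#' @param grid A [window_grid()].
#' @param shift_bp Center shift (default 75).
#' @param dedup Collapse identical records before shifting (default FALSE;
#'   the sperm libraries were filtered upstream by alignment score, the
#'   somatic-style workflow de-duplicates).
#' @return Integer vector of per-window center counts.
#' @export
center_counts <- function(reads, grid, shift_bp = 75L, dedup = FALSE) {
  .check_reads(reads)
  if (dedup) reads <- dedup_reads(reads)
  centers <- shift_read_to_center(reads, shift_bp)
  count_positions_in_windows(reads$chrom, centers, grid)
}

# run code with a private RNG state seeded by `seed`, restoring the
# caller's state afterwards
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Uniformly subsample reads without replacement
#'
#' Used to depth-match the (deeper) nucleosome library to the genomic
#' input before scoring.  Deterministic for a fixed seed; the caller's RNG
#' state is untouched.
#'
#' @param reads Read data.frame.
#' @param target_total Number of reads to keep.
#' @param seed Integer seed.
#' @return Subsampled data.frame (original row order preserved).
#' @export
subsample_reads <- function(reads, target_total, seed = 1L) {
  .check_reads(reads)
  n <- nrow(reads)
  if (target_total > n) stop("target_total exceeds the number of reads")
  if (target_total == n) return(reads)
  keep <- with_seed(seed, sort(sample.int(n, target_total)))
  reads[keep, , drop = FALSE]
}

#' Normalized nucleosome retention score
#'
#' S = (n - i) / sqrt(n + i): the difference between nucleosome and input
#' read counts in a window divided by the square root of their sum.
#' Undefined (error) when n + i = 0; callers filter such windows first.
#'
#' @param nuc_count,input_count Non-negative integer vectors.
#' @return Numeric score vector.
#' @export
normalized_retention_score <- function(nuc_count, input_count) {
  if (any(nuc_count < 0) || any(input_count < 0))
    stop("counts must be non-negative")
  tot <- nuc_count + input_count
  if (any(tot == 0))
    stop("retention score undefined for windows with zero total reads")
  (nuc_count - input_count) / sqrt(tot)
}

#' Low-coverage window filter
#'
#' @param nuc_count,input_count Per-window counts.
#' @param min_total Minimum total reads (default 5).
#' @return Logical keep vector: TRUE iff nuc + input >= min_total.
#' @export
low_coverage_filter <- function(nuc_count, input_count, min_total = 5L) {
  (nuc_count + input_count) >= min_total
}

#' Per-window retention score track with exclusion flags
#'
#' @param nuc_count,input_count Per-window center counts.
#' @param min_total Low-coverage threshold (default 5).
#' @param excluded Optional logical vector of windows excluded a priori
#'   (repetitive 20-mers, N-containing).
#' @return List with `score` (NA where total = 0), `low_coverage`,
#'   `excluded` and `keep` (= !low_coverage & !excluded).
#' @export
retention_score_track <- function(nuc_count, input_count, min_total = 5L,
                                  excluded = NULL) {
  if (length(nuc_count) != length(input_count))
    stop("count vectors differ in length")
  if (is.null(excluded)) excluded <- rep(FALSE, length(nuc_count))
  tot <- nuc_count + input_count
  score <- rep(NA_real_, length(tot))
  pos <- tot > 0
  score[pos] <- (nuc_count[pos] - input_count[pos]) / sqrt(tot[pos])
  lowcov <- !low_coverage_filter(nuc_count, input_count, min_total)
  list(score = score, low_coverage = lowcov, excluded = excluded,
       keep = !lowcov & !excluded)
}

#' Binomial enrichment score against an input control
#'
#' -log10 of the upper binomial tail P(X >= signal | n = signal + input,
#' p = depth_ratio), used to score modified-nucleosome (H3K4me3/H3K27me3)
#' retention.  Returns 0 when signal = 0 (tail probability 1).  The exact
#' tail form is a package choice; the source data only state that the
#' score is binomial against the input.
#'
#' @param signal_count,input_count Non-negative integer vectors.
#' @param depth_ratio Success probability: signal-library depth over total
#'   depth; must lie in (0, 1).
#' @return Numeric score vector (>= 0), computed on the log scale so deep
#'   enrichment does not underflow.
#' @export
binomial_enrichment_score <- function(signal_count, input_count, depth_ratio) {
  if (any(signal_count < 0) || any(input_count < 0))
    stop("counts must be non-negative")
  if (depth_ratio <= 0 || depth_ratio >= 1)
    stop("depth_ratio must be in (0, 1)")
  n <- signal_count + input_count
  logp <- stats::pbinom(signal_count - 1L, n, depth_ratio,
                        lower.tail = FALSE, log.p = TRUE)
  score <- -logp / log(10)
  score[signal_count == 0] <- 0
  pmax(score, 0)
}

#' Call nucleosome-enrichment regions against the input control
#'
#' Slides a `caller_window_bp` window (step `caller_step_bp`) along each
#' chromosome, counts fragment centers from both libraries, and applies a
#' one-sided binomial test with success probability equal to the
#' nucleosome depth fraction.  Windows with Benjamini-Hochberg adjusted
#' p < `caller_alpha` (and total reads >= `min_total_reads`) are merged
#' when overlapping; each region's score is the max -log10(adjusted p) of
#' its windows.
#'
#' @param nuc_reads,input_reads Read data.frames.
#' @param seqlengths Named chromosome lengths.
#' @param params A [retention_params()].
#' @param dedup Collapse identical records first (default FALSE).
#' @return A `GRanges` of enriched regions with metadata column
#'   `enrichment_score`; empty when nothing passes.
#' @export
call_enriched_regions <- function(nuc_reads, input_reads, seqlengths,
                                  params = retention_params(),
                                  dedup = FALSE) {
  .check_reads(nuc_reads)
  .check_reads(input_reads)
  if (nrow(nuc_reads) == 0 || nrow(input_reads) == 0)
    stop("both read sets must be non-empty")
  step <- params$caller_step_bp
  W <- params$caller_window_bp
  m <- W %/% step
  sgrid <- window_grid(seqlengths, step)
  ncnt <- center_counts(nuc_reads, sgrid, params$shift_bp, dedup)
  icnt <- center_counts(input_reads, sgrid, params$shift_bp, dedup)
  Nn <- sum(ncnt)
  Ni <- sum(icnt)
  if (Ni == 0) stop("zero input depth within the genome")
  p0 <- Nn / (Nn + Ni)
  ch_all <- st_all <- list()
  n_all <- t_all <- list()
  for (ch in names(sgrid$seqlengths)) {
    nw <- sgrid$nwin[[ch]]
    if (nw < m) next
    sel <- seq.int(sgrid$offset[[ch]] + 1L, length.out = nw)
    csn <- c(0L, cumsum(ncnt[sel]))
    csi <- c(0L, cumsum(icnt[sel]))
    ns <- nw - m + 1L
    i0 <- seq_len(ns)
    nw300 <- csn[i0 + m] - csn[i0]
    iw300 <- csi[i0 + m] - csi[i0]
    ch_all[[ch]] <- rep(ch, ns)
    st_all[[ch]] <- (i0 - 1L) * step
    n_all[[ch]] <- nw300
    t_all[[ch]] <- nw300 + iw300
  }
  chv <- unlist(ch_all, use.names = FALSE)
  stv <- unlist(st_all, use.names = FALSE)
  nv <- unlist(n_all, use.names = FALSE)
  tv <- unlist(t_all, use.names = FALSE)
  test <- tv >= params$min_total_reads
  if (!any(test))
    return(GenomicRanges::GRanges(seqlengths = sgrid$seqlengths,
                                  enrichment_score = numeric(0)))
  logp <- stats::pbinom(nv[test] - 1L, tv[test], p0,
                        lower.tail = FALSE, log.p = TRUE)
  padj <- stats::p.adjust(exp(logp), method = "BH")
  sig <- padj < params$caller_alpha
  if (!any(sig))
    return(GenomicRanges::GRanges(seqlengths = sgrid$seqlengths,
                                  enrichment_score = numeric(0)))
  score <- -log10(padj[sig])
  wins <- GenomicRanges::GRanges(
    seqnames = chv[test][sig],
    ranges = IRanges::IRanges(start = stv[test][sig] + 1L, width = W),
    seqlengths = sgrid$seqlengths)
  merged <- GenomicRanges::reduce(wins)
  hits <- GenomicRanges::findOverlaps(merged, wins)
  ms <- tapply(score[S4Vectors::subjectHits(hits)],
               S4Vectors::queryHits(hits), max)
  S4Vectors::mcols(merged)$enrichment_score <-
    as.numeric(ms[as.character(seq_along(merged))])
  sort(merged)
}
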