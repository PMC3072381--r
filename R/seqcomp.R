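# Windowed base-composition tracks, k-mer uniqueness masks, and
# CpG-island detection from a genome sequence.

# base -> 2-bit code lookup (A=0, C=1, G=2, T=3; anything else NA).
# Input sequence is expected uppercase (read_genome_fasta() normalizes).
.base_codes <- local({
  z <- rep(NA_integer_, 256L)
  z[utf8ToInt("A")] <- 0L
  z[utf8ToInt("C")] <- 1L
  z[utf8ToInt("G")] <- 2L
  z[utf8ToInt("T")] <- 3L
  z
})

.encode_bases <- function(seqchar) .base_codes[utf8ToInt(seqchar)]

#' Per-window base composition
#'
#' Counts, for every window of the grid, the number of G+C bases, the
#' number of CpG ("CG") dinucleotides fully inside the window (a CG
#' straddling a window boundary is not counted), and the number of N
#' bases.
#'
#' @param genome A `DNAStringSet`.
#' @param grid A [window_grid()] derived from `genome`.
#' @return A `composition_track`: list with the grid and integer vectors
#'   `gc`, `cpg`, `n` aligned to the grid, plus `unique20 = NULL` until
#'   [kmer_uniqueness_mask()] is attached.
#' @export
window_base_counts <- function(genome, grid) {
  stopifnot(inherits(grid, "window_grid"))
  chroms <- names(grid$seqlengths)
  if (!all(chroms %in% names(genome)))
    stop("grid references chromosomes absent from the genome")
  if (any(grid$seqlengths > Biostrings::width(genome)[match(chroms, names(genome))]))
    stop("grid windows extend beyond chromosome ends")
  gc <- cpg <- nn <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    nw <- grid$nwin[[ch]]
    if (nw == 0L) {
      gc[[i]] <- cpg[[i]] <- nn[[i]] <- integer(0)
      next
    }
    v <- Biostrings::Views(
      genome[[ch]],
      start = seq(1L, by = grid$width, length.out = nw),
      width = grid$width)
    lf <- Biostrings::letterFrequency(v, c("G", "C", "N"))
    gc[[i]] <- as.integer(lf[, "G"] + lf[, "C"])
    nn[[i]] <- as.integer(lf[, "N"])
    # per-window sequences so a CG can never be counted across a boundary
    cpg[[i]] <- Biostrings::vcountPattern("CG", methods::as(v, "DNAStringSet"))
  }
  structure(
    list(grid = grid,
         gc = unlist(gc, use.names = FALSE),
         cpg = unlist(cpg, use.names = FALSE),
         n = unlist(nn, use.names = FALSE),
         unique20 = NULL),
    class = "composition_track")
}

#' @export
print.composition_track <- function(x, ...) {
  cat("composition_track over", x$grid$n, "windows of", x$grid$width, "bp;",
      "mean GC fraction", round(mean(x$gc) / x$grid$width, 3), "\n")
  invisible(x)
}

#' Per-window k-mer uniqueness mask
#'
#' A window is unique iff every k-mer fully inside it occurs exactly once
#' in the genome, counting occurrences of the k-mer and of its reverse
#' complement across all chromosomes (mappability of unstranded short
#' reads).  k-mers containing N are treated as non-unique.
#'
#' k-mers are 2-bit encoded into doubles (exact up to k = 26) with a
#' linear-filter rolling encoding, so the mask is computed in vectorized
#' passes rather than per-window loops.
#'
#' @param genome A `DNAStringSet`.
#' @param grid A [window_grid()].
#' @param k k-mer length, default 20.
#' @return Logical vector aligned to the grid: TRUE = all k-mers in the
#'   window are unique.
#' @export
kmer_uniqueness_mask <- function(genome, grid, k = 20L) {
  stopifnot(inherits(grid, "window_grid"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > grid$width)
    stop("k must be in 1..window width")
  if (k > 26L) stop("k > 26 exceeds exact double encoding")
  chroms <- names(grid$seqlengths)
  fwd_w <- 4^(0:(k - 1L))
  rc_w <- 4^((k - 1L):0)
  canon <- vector("list", length(chroms))
  names(canon) <- chroms
  for (ch in chroms) {
    code <- .encode_bases(as.character(genome[[ch]]))
    L <- length(code)
    if (L < k) {
      canon[[ch]] <- numeric(0)
      next
    }
    f <- as.numeric(stats::filter(code, fwd_w, sides = 1))
    r <- as.numeric(stats::filter(3L - code, rc_w, sides = 1))
    # canonical code of the k-mer starting at position i (1-based)
    canon[[ch]] <- pmin(f, r)[k:L]
  }
  allc <- unlist(canon, use.names = FALSE)
  nonuniq <- duplicated(allc) | duplicated(allc, fromLast = TRUE)
  nonuniq[is.na(allc)] <- TRUE
  # split back per chromosome and reduce to windows
  lens <- lengths(canon)
  ends <- cumsum(lens)
  out <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    nw <- grid$nwin[[ch]]
    if (nw == 0L) {
      out[[i]] <- logical(0)
      next
    }
    nu <- nonuniq[seq.int(ends[i] - lens[i] + 1L, length.out = lens[i])]
    cs <- c(0, cumsum(nu))
    st <- (seq_len(nw) - 1L) * grid$width + 1L # first k-mer start (1-based)
    en <- st + grid$width - k                  # last k-mer start fully inside
    out[[i]] <- (cs[pmin(en, lens[i]) + 1L] - cs[st]) == 0
  }
  unlist(out, use.names = FALSE)
}

#' Detect CpG islands by the classical composition definition
#'
#' Maximal intervals of length >= `min_len` with GC fraction >= `min_gc`
#' and observed/expected CpG ratio `(#CpG * L) / (#C * #G)` >= `min_oe`
#' (defaults: 200 bp, 0.5, 0.6).  Qualifying `min_len`-bp seed windows are
#' merged greedily left to right while the merged interval still satisfies
#' all thresholds; output intervals never overlap.
#'
#' @param genome A `DNAStringSet`.
#' @param min_len Minimum island length (bp).
#' @param min_gc Minimum GC fraction.
#' @param min_oe Minimum observed/expected CpG ratio.
#' @return A sorted `GRanges` (1-based closed) with metadata columns
#'   `gc_fraction` and `obs_exp_cpg`.
#' @export
detect_cpg_islands <- function(genome, min_len = 200L, min_gc = 0.5,
                               min_oe = 0.6) {
  min_len <- as.integer(min_len)
  if (min_len < 2L || min_gc <= 0 || min_oe <= 0)
    stop("island thresholds must be positive (and min_len >= 2)")
  res_ch <- character(0)
  res_a <- res_b <- integer(0)
  res_gc <- res_oe <- numeric(0)
  for (ch in names(genome)) {
    L <- Biostrings::width(genome)[match(ch, names(genome))]
    if (L < min_len) next
    code <- .encode_bases(as.character(genome[[ch]]))
    isC <- !is.na(code) & code == 1L
    isG <- !is.na(code) & code == 2L
    isCG <- isC[-L] & isG[-1L]
    cC <- c(0L, cumsum(isC))
    cG <- c(0L, cumsum(isG))
    cCG <- c(0L, cumsum(isCG))
    # stats of 1-based inclusive interval [a, b]; CpGs counted fully inside
    istat <- function(a, b) {
      nC <- cC[b + 1L] - cC[a]
      nG <- cG[b + 1L] - cG[a]
      nCG <- cCG[b] - cCG[a]
      len <- b - a + 1L
      gcf <- (nC + nG) / len
      oe <- ifelse(nC * nG > 0L, nCG * len / (nC * nG), 0)
      list(gc = gcf, oe = oe)
    }
    a_all <- seq_len(L - min_len + 1L)
    s <- istat(a_all, a_all + min_len - 1L)
    qs <- a_all[s$gc >= min_gc & s$oe >= min_oe]
    nq <- length(qs)
    # clusters of seeds chained by overlap/adjacency
    cl_start <- which(c(TRUE, diff(qs) > min_len))
    cl_end <- c(cl_start[-1L] - 1L, nq)
    for (cidx in seq_along(cl_start)) {
      i <- cl_start[cidx]
      last <- cl_end[cidx]
      while (i <= last) {
        a <- qs[i]
        b <- a + min_len - 1L
        j <- i + 1L
        # fast path: the whole remaining cluster merges in one step
        bc <- qs[last] + min_len - 1L
        stc <- istat(a, bc)
        if (stc$gc >= min_gc && stc$oe >= min_oe) {
          b <- bc
          j <- last + 1L
        } else {
          while (j <= last && qs[j] <= b + 1L) {
            b2 <- max(b, qs[j] + min_len - 1L)
            st2 <- istat(a, b2)
            if (st2$gc >= min_gc && st2$oe >= min_oe) {
              b <- b2
              j <- j + 1L
            } else break
          }
        }
        fin <- istat(a, b)
        res_ch <- c(res_ch, ch)
        res_a <- c(res_a, a)
        res_b <- c(res_b, b)
        res_gc <- c(res_gc, fin$gc)
        res_oe <- c(res_oe, fin$oe)
        while (j <= last && qs[j] <= b) j <- j + 1L
        i <- j
      }
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = res_ch,
    ranges = IRanges::IRanges(start = res_a, end = res_b),
    gc_fraction = res_gc, obs_exp_cpg = res_oe)
  GenomeInfoDb::seqlevels(gr) <- names(genome)
  sort(gr)
}
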