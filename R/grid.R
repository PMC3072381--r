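# Window grid: the genome tiled into fixed-width, non-overlapping windows.
#
# Window starts are 0-based; a window i on a chromosome covers
# [i*width, (i+1)*width) in 0-based half-open coordinates.  A trailing
# partial window is dropped.  Interval containers handed to/returned from
# the Bioconductor layer (GRanges) are 1-based closed, as usual in R;
# conversion happens only at those boundaries.

#' Tile chromosomes into fixed non-overlapping windows
#'
#' @param seqlengths Named integer vector of chromosome lengths (bp).
#' @param width Window width in bp (default 150).
#' @return A `window_grid` object: per chromosome, `floor(len/width)`
#'   windows starting at 0, width, 2*width, ...; the trailing partial
#'   window is dropped.
#' @export
window_grid <- function(seqlengths, width = 150L) {
  width <- as.integer(width)
  if (length(width) != 1L || is.na(width) || width < 1L)
    stop("window width must be a positive integer")
  if (is.null(names(seqlengths)) || any(names(seqlengths) == "") ||
      anyDuplicated(names(seqlengths)))
    stop("seqlengths must be uniquely named")
  sl <- as.integer(seqlengths)
  if (any(is.na(sl)) || any(sl <= 0L)) stop("chromosome lengths must be > 0")
  names(sl) <- names(seqlengths)
  nwin <- sl %/% width
  offset <- c(0L, cumsum(nwin))[seq_along(nwin)]
  names(offset) <- names(sl)
  structure(
    list(seqlengths = sl, width = width, nwin = nwin, offset = offset,
         n = sum(nwin)),
    class = "window_grid")
}

#' Tile a genome into fixed windows
#'
#' @param genome A `DNAStringSet` with one entry per chromosome.
#' @param width Window width in bp.
#' @return A [window_grid()].
#' @export
make_windows <- function(genome, width = 150L) {
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet")
  window_grid(stats::setNames(Biostrings::width(genome), names(genome)), width)
}

#' @export
print.window_grid <- function(x, ...) {
  cat("window_grid:", length(x$seqlengths), "chromosome(s),",
      x$n, "windows of", x$width, "bp\n")
  invisible(x)
}

#' Map genomic positions to global window indices
#'
#' @param grid A `window_grid`.
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 0-based positions.
#' @return Integer vector of 1-based global window indices; `NA` for
#'   positions outside the grid (unknown chromosome, negative, or in the
#'   dropped trailing partial window).
#' @export
window_index <- function(grid, chrom, pos) {
  stopifnot(inherits(grid, "window_grid"))
  off <- grid$offset[chrom]
  nw <- grid$nwin[chrom]
  w <- pos %/% grid$width
  idx <- unname(off) + w + 1L
  idx[is.na(off) | pos < 0L | w >= unname(nw)] <- NA_integer_
  as.integer(idx)
}

# chromosome name of each window, as a character vector aligned to the grid
window_chroms <- function(grid) {
  rep(names(grid$seqlengths), grid$nwin)
}

# 0-based start of each window
window_starts <- function(grid) {
  unlist(lapply(grid$nwin, function(n) {
    if (n == 0L) integer(0) else (seq_len(n) - 1L) * grid$width
  }), use.names = FALSE)
}

#' Windows of a grid as a GRanges (1-based closed coordinates)
#'
#' @param grid A `window_grid`.
#' @return A `GRanges` with one range per window, in grid order.
#' @export
grid_ranges <- function(grid) {
  stopifnot(inherits(grid, "window_grid"))
  st <- window_starts(grid)
  GenomicRanges::GRanges(
    seqnames = window_chroms(grid),
    ranges = IRanges::IRanges(start = st + 1L, width = grid$width),
    seqlengths = grid$seqlengths)
}
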