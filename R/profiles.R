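# Anchor-centered average profiles and per-gene heatmap matrices:
# ~4-kb spans around TSSs (or interval midpoints) in 150-bp bins.

# relative bin offsets for a span: an odd number of bins centered on the
# anchor-containing bin (4,000 bp at 150-bp bins -> 27 bins = 4,050 bp)
.profile_offsets <- function(span, bin) {
  nb <- ceiling(span / bin)
  if (nb %% 2L == 0L) nb <- nb + 1L
  half <- (nb - 1L) %/% 2L
  (-half):half
}

# per-anchor matrix of track values in relative bins (anchors x bins);
# minus-strand anchors are flipped so +offsets point downstream of
# transcription.  Out-of-range or masked-out windows give NA.
.anchor_matrix <- function(values, grid, anchors, span, bin, mask = NULL) {
  stopifnot(inherits(grid, "window_grid"))
  if (bin != grid$width) stop("profile bin must equal the grid width")
  if (nrow(anchors) == 0L) stop("empty anchor list")
  if (!is.null(mask)) values[!mask] <- NA_real_
  rel <- .profile_offsets(span, bin)
  aw <- window_index(grid, anchors$chrom, anchors$pos)
  flip <- anchors$strand == "-"
  idx <- outer(aw, rel, "+")
  idx[flip, ] <- idx[flip, rev(seq_along(rel)), drop = FALSE]
  # windows must stay on the anchor's chromosome
  chlo <- grid$offset[anchors$chrom] + 1L
  chhi <- grid$offset[anchors$chrom] + grid$nwin[anchors$chrom]
  bad <- idx < chlo | idx > chhi | is.na(idx)
  idx[bad] <- 1L
  m <- matrix(values[idx], nrow = nrow(anchors))
  m[bad] <- NA_real_
  colnames(m) <- rel * bin
  m
}

#' Average profile of a window track around anchors
#'
#' Lays an odd number of `bin`-bp bins (covering at least `span` bp,
#' default 27 x 150 = 4,050 bp) around each anchor's window, flips
#' minus-strand anchors so downstream = transcription direction, and
#' averages over anchors per relative bin, skipping out-of-range or
#' masked windows.
#'
#' @param values Numeric per-window track.
#' @param grid The [window_grid()] the track is aligned to.
#' @param anchors data.frame (chrom, pos, strand); pos 0-based.
#' @param span Profile span in bp (default 4000).
#' @param bin Bin width; must equal the grid width (default 150).
#' @param mask Optional logical keep vector for windows.
#' @return data.frame (offset_bp, mean, n) with one row per relative bin;
#'   `n` counts the anchors contributing to the bin.
#' @export
meta_profile <- function(values, grid, anchors, span = 4000L, bin = 150L,
                         mask = NULL) {
  m <- .anchor_matrix(values, grid, anchors, span, bin, mask)
  data.frame(offset_bp = as.integer(colnames(m)),
             mean = colMeans(m, na.rm = TRUE),
             n = colSums(!is.na(m)),
             row.names = NULL)
}

#' Per-gene profile matrix with optional clustering order
#'
#' One row per gene (anchored at its canonical TSS), one column per
#' relative bin.  When `order_by` is given (a companion matrix over the
#' same genes, e.g. the GC-content matrix), rows are re-ordered by the
#' leaf order of average-linkage hierarchical clustering (Euclidean
#' distance) of `order_by`, so paired matrices share one ordering.
#'
#' @param values Numeric per-window track.
#' @param grid The [window_grid()].
#' @param genes Gene-model data.frame (gene_id, chrom, strand, tss, ...).
#' @param span,bin Profile geometry (defaults 4000/150).
#' @param mask Optional logical keep vector.
#' @param order_by Optional numeric matrix (same genes, same row order)
#'   whose clustering dictates the row order.
#' @return Numeric matrix with gene_id rownames, re-ordered when
#'   `order_by` is given; the ordering permutation in attr "order".
#' @export
gene_profile_matrix <- function(values, grid, genes, span = 4000L,
                                bin = 150L, mask = NULL, order_by = NULL) {
  anchors <- data.frame(chrom = genes$chrom, pos = genes$tss,
                        strand = genes$strand)
  m <- .anchor_matrix(values, grid, anchors, span, bin, mask)
  rownames(m) <- genes$gene_id
  ord <- seq_len(nrow(m))
  if (!is.null(order_by)) {
    if (nrow(order_by) != nrow(m)) stop("order_by has mismatched rows")
    ob <- order_by
    ob[is.na(ob)] <- 0
    ord <- stats::hclust(stats::dist(ob), method = "average")$order
    m <- m[ord, , drop = FALSE]
  }
  attr(m, "order") <- ord
  m
}
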