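# Gene models, expression-based gene classes, retained-at-TSS calls,
# genomic location of retention regions, and distal-site filtering.
#
# Gene models are data frames: gene_id, chrom, strand, tss, tes (tss/tes
# 0-based point coordinates; for "-" genes tss > tes).  Transcript start
# sites live in a companion data frame (gene_id, tss).

.check_genes <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "tss", "tes")
  if (!is.data.frame(genes) || !all(need %in% names(genes)))
    stop("genes must be a data.frame with columns ", paste(need, collapse = ", "))
  if (any(genes$tss == genes$tes)) stop("tss must differ from tes")
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be '+'/'-'")
  invisible(genes)
}

# distance (bp) from 0-based point positions to sorted, non-overlapping
# 0-based half-open intervals on one chromosome; 0 when inside, otherwise
# the gap to the nearest boundary coordinate. Inf when no interval.
.point_interval_dist <- function(pos, s0, e0) {
  if (length(s0) == 0L) return(rep(Inf, length(pos)))
  k <- findInterval(pos, s0)
  kl <- pmax(k, 1L)
  dl <- ifelse(k >= 1L,
               ifelse(pos < e0[kl], 0, pos - e0[kl]),
               Inf)
  kr <- pmin(k + 1L, length(s0))
  dr <- ifelse(k < length(s0), s0[kr] - pos, Inf)
  pmin(dl, dr)
}

# per-point minimum distance to regions (GRanges, any overlap structure);
# regions are reduced internally so the sorted/non-overlapping assumption
# of .point_interval_dist holds.
.min_dist_points_regions <- function(chrom, pos, regions) {
  d <- rep(Inf, length(pos))
  red <- GenomicRanges::reduce(regions)
  sn <- as.character(GenomeInfoDb::seqnames(red))
  for (ch in unique(chrom)) {
    sel <- sn == ch
    idx <- which(chrom == ch)
    s0 <- GenomicRanges::start(red)[sel] - 1L
    e0 <- GenomicRanges::end(red)[sel]
    d[idx] <- .point_interval_dist(pos[idx], s0, e0)
  }
  d
}

#' Is a gene's start site retained?
#'
#' TRUE iff any of the gene's transcript start sites lies inside an
#' enrichment region or within `max_dist` bp of its nearest boundary
#' (inclusive at exactly `max_dist`; inside counts as distance 0).
#'
#' @param genes Gene-model data.frame.
#' @param transcripts data.frame (gene_id, tss) of all transcript start
#'   sites; defaults to the genes' own tss.
#' @param regions `GRanges` of retention regions.
#' @param max_dist Distance threshold in bp (default 50).
#' @return Named logical vector, one entry per gene in `genes` order.
#' @export
tss_retained <- function(genes, regions, transcripts = NULL, max_dist = 50L) {
  .check_genes(genes)
  if (is.null(transcripts))
    transcripts <- data.frame(gene_id = genes$gene_id, tss = genes$tss)
  tr <- merge(transcripts, genes[c("gene_id", "chrom")], by = "gene_id")
  d <- .min_dist_points_regions(tr$chrom, tr$tss, regions)
  hit <- tapply(d <= max_dist, tr$gene_id, any)
  out <- as.logical(hit[genes$gene_id])
  out[is.na(out)] <- FALSE
  names(out) <- genes$gene_id
  out
}

#' Classify retention regions by genomic location
#'
#' Each region gets one label with precedence TSS > TES > other_genic >
#' non_genic: TSS/TES when the region is within `max_dist` bp of any
#' transcript start/gene end site (overlap = distance 0), other_genic
#' when it intersects any gene span (min(tss,tes)..max(tss,tes)).
#'
#' @param regions `GRanges` of retention regions.
#' @param genes Gene-model data.frame.
#' @param transcripts Optional transcript TSS data.frame (gene_id, tss).
#' @param max_dist Distance threshold (default 50).
#' @return Factor of labels aligned to `regions`, levels
#'   c("TSS", "TES", "other_genic", "non_genic").
#' @export
classify_region_location <- function(regions, genes, transcripts = NULL,
                                     max_dist = 50L) {
  .check_genes(genes)
  if (is.null(transcripts))
    transcripts <- data.frame(gene_id = genes$gene_id, tss = genes$tss)
  tr <- merge(transcripts, genes[c("gene_id", "chrom")], by = "gene_id")
  rch <- as.character(GenomeInfoDb::seqnames(regions))
  rs0 <- GenomicRanges::start(regions) - 1L
  re0 <- GenomicRanges::end(regions)
  near_points <- function(pch, ppos) {
    d <- rep(Inf, length(regions))
    for (ch in unique(pch)) {
      pp <- sort(ppos[pch == ch])
      if (length(pp) == 0L) next
      idx <- which(rch == ch)
      if (length(idx) == 0L) next
      s <- rs0[idx]; e <- re0[idx]
      # nearest point: last point <= e-1 and its successor
      j <- findInterval(e - 1L, pp)
      jl <- pmax(j, 1L)
      dl <- ifelse(j >= 1L,
                   ifelse(pp[jl] >= s, 0, s - pp[jl]),
                   Inf)
      jr <- pmin(j + 1L, length(pp))
      dr <- ifelse(j < length(pp), pp[jr] - e, Inf)
      d[idx] <- pmin(dl, dr)
    }
    d
  }
  d_tss <- near_points(tr$chrom, tr$tss)
  d_tes <- near_points(genes$chrom, genes$tes)
  spans <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = pmin(genes$tss, genes$tes) + 1L,
                              end = pmax(genes$tss, genes$tes)))
  genic <- suppressWarnings(GenomicRanges::countOverlaps(regions, spans)) > 0
  lab <- ifelse(d_tss <= max_dist, "TSS",
         ifelse(d_tes <= max_dist, "TES",
         ifelse(genic, "other_genic", "non_genic")))
  factor(lab, levels = c("TSS", "TES", "other_genic", "non_genic"))
}

#' Expression breadth
#'
#' Number of tissues in which a gene's RPKM is at or above the threshold.
#'
#' @param rpkm Numeric matrix, genes x tissues, rownames = gene ids.
#' @param threshold Expression threshold (default 0.5 RPKM, inclusive).
#' @return Named integer vector of breadths.
#' @export
expression_breadth <- function(rpkm, threshold = 0.5) {
  if (!is.matrix(rpkm) || is.null(rownames(rpkm)))
    stop("rpkm must be a matrix with gene-id rownames")
  rowSums(rpkm >= threshold)
}

#' Classify genes by expression breadth and GO annotation
#'
#' Labels may co-occur and are reported as logical columns:
#' * housekeeping: in `hk_list` when supplied, else breadth = #tissues;
#' * tissue_specific: breadth = 1;
#' * developmental_TF: annotated with GO:0006355 AND any GO term name
#'   containing the word "development" (case-insensitive).
#'
#' @param rpkm Genes x tissues RPKM matrix (gene-id rownames).
#' @param go data.frame (gene_id, term_id, term_name) of flat GO labels.
#' @param hk_list Optional character vector of housekeeping gene ids.
#' @param threshold RPKM expression threshold (default 0.5).
#' @return data.frame (gene_id, breadth, housekeeping, tissue_specific,
#'   developmental_TF), one row per gene in the rpkm matrix.
#' @export
classify_genes <- function(rpkm, go = NULL, hk_list = NULL, threshold = 0.5) {
  br <- expression_breadth(rpkm, threshold)
  ids <- rownames(rpkm)
  hk <- if (is.null(hk_list)) br == ncol(rpkm) else ids %in% hk_list
  ts <- br == 1L
  dev <- rep(FALSE, length(ids))
  if (!is.null(go) && nrow(go) > 0) {
    has_tf <- ids %in% go$gene_id[go$term_id == "GO:0006355"]
    has_dev <- ids %in%
      go$gene_id[grepl("development", go$term_name, ignore.case = TRUE)]
    dev <- has_tf & has_dev
  }
  data.frame(gene_id = ids, breadth = as.integer(br),
             housekeeping = unname(hk), tissue_specific = unname(ts),
             developmental_TF = dev, row.names = NULL)
}

#' mRNA present in mature sperm?
#'
#' @param calls Logical matrix, genes x 13 donors (or a single gene's
#'   13-vector): present/absent detection calls.
#' @param min_donors Minimum donors with a present call (default 7).
#' @param n_donors Expected donor count (default 13).
#' @return Logical vector: TRUE iff present in >= `min_donors` donors.
#' @export
sperm_mrna_present <- function(calls, min_donors = 7L, n_donors = 13L) {
  if (is.vector(calls)) calls <- matrix(calls, nrow = 1)
  if (ncol(calls) != n_donors)
    stop("expected ", n_donors, " donor columns, got ", ncol(calls))
  rowSums(calls) >= min_donors
}

#' Bin genes for a trend test
#'
#' Sorts genes by a key (ties broken by stable gene-id order) and splits
#' them into `n_bins` contiguous equal-size bins, the remainder going to
#' the last bin.
#'
#' @param gene_id Character vector.
#' @param sort_key Numeric sort key (e.g. expression level).
#' @param retained Logical success indicator per gene.
#' @param n_bins Number of bins.
#' @return data.frame (bin, score, total, successes) with score = bin
#'   index 0..n_bins-1.
#' @export
bin_genes_for_trend <- function(gene_id, sort_key, retained, n_bins = 10L) {
  n <- length(gene_id)
  if (n == 0L) stop("empty gene set")
  if (n_bins > n) stop("more bins than genes")
  o <- order(sort_key, gene_id)
  size <- n %/% n_bins
  bin <- pmin(((seq_len(n) - 1L) %/% size) + 1L, n_bins)
  ret <- retained[o]
  data.frame(bin = seq_len(n_bins),
             score = seq_len(n_bins) - 1L,
             total = as.integer(tabulate(bin, n_bins)),
             successes = as.integer(tapply(ret, bin, sum)))
}

#' Keep only sites distal to all genes
#'
#' Retains intervals whose distance to the nearest gene span
#' (min(tss,tes)..max(tss,tes)) is at least `min_dist` bp; overlapping
#' sites have distance 0 and are removed.
#'
#' @param sites `GRanges` of candidate sites.
#' @param genes Gene-model data.frame.
#' @param min_dist Minimum distance in bp (default 1000, inclusive).
#' @return Filtered `GRanges`.
#' @export
filter_distal_sites <- function(sites, genes, min_dist = 1000L) {
  .check_genes(genes)
  spans <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = pmin(genes$tss, genes$tes) + 1L,
                              end = pmax(genes$tss, genes$tes)))
  hits <- suppressWarnings(GenomicRanges::distanceToNearest(sites, spans))
  d <- rep(Inf, length(sites))
  # IRanges distance between disjoint ranges equals the 0-based boundary
  # gap; overlap gives 0
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  sites[d >= min_dist]
}
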