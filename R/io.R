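# Readers/writers for the plain-text formats the pipeline exchanges:
# FASTA genomes, BED intervals, read tables, window-track / gene tables.
# BED is 0-based half-open on disk; GRanges are 1-based closed in memory.

#' Read a (multi-record, wrapped, case-insensitive) FASTA genome
#'
#' @param path FASTA file.
#' @return `DNAStringSet`, uppercased.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  # normalize case and strip description from the record id
  names(x) <- sub("\\s.*$", "", names(x))
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Write a genome FASTA
#' @param genome `DNAStringSet`.
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
}

#' Read intervals from BED (3 or 6+ columns)
#'
#' @param path BED file (0-based half-open).
#' @return `GRanges` (1-based closed); columns 4/5 become `name`/`score`.
#' @export
read_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = d[[1]],
    ranges = IRanges::IRanges(start = d[[2]] + 1L, end = d[[3]]))
  if (ncol(d) >= 4) S4Vectors::mcols(gr)$name <- d[[4]]
  if (ncol(d) >= 5) S4Vectors::mcols(gr)$score <- d[[5]]
  if (ncol(d) >= 6) GenomicRanges::strand(gr) <- d[[6]]
  gr
}

#' Write intervals to BED
#'
#' @param gr `GRanges`; a `score`-like metadata column (given by
#'   `score_col`) is written as BED column 5.
#' @param path Output file.
#' @param score_col Name of the metadata column to use as score.
#' @export
write_bed <- function(gr, path, score_col = NULL) {
  d <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr))
  if (!is.null(score_col)) {
    d$name <- paste0("region_", seq_along(gr))
    d$score <- S4Vectors::mcols(gr)[[score_col]]
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read 5'-end read records
#'
#' Accepts a 3-column TSV (chrom, five_prime, strand; 0-based, with or
#' without header) or BED6 (the minus-strand 5' end is `end - 1`).
#'
#' @param path Input file.
#' @param format "tsv" or "bed6".
#' @return Read data.frame (chrom, pos, strand).
#' @export
read_reads <- function(path, format = c("tsv", "bed6")) {
  format <- match.arg(format)
  if (format == "bed6") {
    d <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    if (ncol(d) < 6) stop("BED6 requires 6 columns")
    pos <- ifelse(d[[6]] == "+", d[[2]], d[[3]] - 1L)
    return(data.frame(chrom = d[[1]], pos = as.integer(pos),
                      strand = d[[6]]))
  }
  first <- readLines(path, n = 1L)
  header <- grepl("chrom", first)
  d <- utils::read.table(path, sep = "\t", header = header,
                         stringsAsFactors = FALSE)
  names(d)[1:3] <- c("chrom", "pos", "strand")
  d$pos <- as.integer(d$pos)
  .check_reads(d[c("chrom", "pos", "strand")])
}

#' Write 5'-end read records as TSV
#' @param reads Read data.frame.
#' @param path Output file.
#' @export
write_reads <- function(reads, path) {
  utils::write.table(
    data.frame(chrom = reads$chrom, pos = reads$pos, strand = reads$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
}

#' Write a window composition/score table as TSV
#'
#' Columns: chrom, start, end (0-based half-open) plus one column per
#' supplied track.
#'
#' @param grid A [window_grid()].
#' @param tracks Named list of per-window vectors.
#' @param path Output file.
#' @export
write_window_tsv <- function(grid, tracks, path) {
  st <- window_starts(grid)
  d <- data.frame(chrom = window_chroms(grid), start = st,
                  end = st + grid$width)
  for (nm in names(tracks)) d[[nm]] <- tracks[[nm]]
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Read gene models from a 6-column TSV
#'
#' Columns gene_id, chrom, strand, tss, tes (0-based points) and
#' optionally class.
#'
#' @param path Input file (with header).
#' @return Gene-model data.frame.
#' @export
read_genes_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  .check_genes(d)
}

#' Write gene models as TSV
#' @param genes Gene-model data.frame.
#' @param path Output file.
#' @export
write_genes_tsv <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Read a genes x columns numeric matrix from TSV (first column = id)
#' @param path Input file (with header).
#' @return Numeric matrix with gene-id rownames.
#' @export
read_matrix_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Write a named matrix as TSV (first column = id)
#' @param m Matrix with rownames.
#' @param path Output file.
#' @param id_col Name of the id column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  d <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(d)[1] <- id_col
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}
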