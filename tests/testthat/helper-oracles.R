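# Fixture builders and independent brute-force oracles used across the
# suite.  Oracles are deliberately naive (enumeration / quadratic loops)
# and never share code with the implementation paths they check.

make_genome <- function(...) {
  Biostrings::DNAStringSet(toupper(unlist(list(...))))
}

random_genome <- function(lens, seed, gc = 0.5) {
  set.seed(seed)
  Biostrings::DNAStringSet(vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }, character(1)))
}

reads_df <- function(chrom, pos, strand) {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand)
}

gr <- function(chrom, start0, end0, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1L, end = end0), ...)
}

# brute-force k-mer window uniqueness: hash every k-mer (and reverse
# complement) with substring, count in an environment-free table
oracle_kmer_unique <- function(genome, width, k) {
  seqs <- as.character(genome)
  kmers <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1), k:L)
  }), use.names = FALSE)
  out <- logical(0)
  for (s in seqs) {
    L <- nchar(s)
    nw <- L %/% width
    for (w in seq_len(nw)) {
      a <- (w - 1) * width + 1
      ks <- substring(s, a:(a + width - k), (a + k - 1):(a + width - 1))
      u <- all(!grepl("N", ks)) &&
        all(vapply(ks, function(km) {
          tot <- sum(kmers == km) +
            sum(kmers == as.character(Biostrings::reverseComplement(Biostrings::DNAString(km))))
          tot == 1 ||
            # a palindromic k-mer occurring once counts itself twice
            (km == as.character(Biostrings::reverseComplement(Biostrings::DNAString(km))) && tot == 2)
        }, logical(1)))
      out <- c(out, u)
    }
  }
  out
}

# quadratic pairwise AUC with half-credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# trapezoidal area under an roc_result's points
trapezoid_area <- function(pts) {
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
}

# build a region GRanges and island GRanges realizing given 2x2 counts:
# islands are disjoint 100-bp intervals; "retained" islands each overlap
# a region
contingency_fixture <- function(unmeth_ret, unmeth_not, meth_ret, meth_not) {
  n <- unmeth_ret + unmeth_not + meth_ret + meth_not
  starts <- (seq_len(n) - 1L) * 1000L
  lab <- rep(c("unmethylated", "unmethylated", "methylated", "methylated"),
             c(unmeth_ret, unmeth_not, meth_ret, meth_not))
  ret <- rep(c(TRUE, FALSE, TRUE, FALSE),
             c(unmeth_ret, unmeth_not, meth_ret, meth_not))
  islands <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(starts + 1L, width = 100L),
                     methylation = lab)
  regions <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(starts[ret] + 50L, width = 100L))
  list(islands = islands, regions = regions)
}
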