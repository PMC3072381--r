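# Synthetic genome / read / annotation generator.
#
# Emulates the statistical structure the analysis assumes: a CpG-depleted
# background genome carrying class-specific promoter architecture (sharp
# CpG islands at housekeeping genes, broad GC-rich domains at
# developmental regulators, AT-rich tissue-specific promoters);
# nucleosome-fraction reads whose per-window sampling weight grows with
# GC; input reads with a mild GC bias; a 10-tissue RPKM matrix; 13-donor
# sperm mRNA presence calls; and island methylation labels correlated
# with retention.  Everything is a deterministic function of
# (config, seed).

#' Configuration of the synthetic-data generator
#'
#' Defaults give a 5-Mb two-chromosome genome with 300 genes, strong
#' GC-to-nucleosome coupling (beta = 4) and a mild input GC bias
#' (gamma = 0.5), sized so the full pipeline runs in well under 5 minutes
#' on one CPU.
#'
#' @param chrom_lengths Named chromosome lengths (bp, each >= 10 kb).
#' @param background_gc Background GC fraction.
#' @param cpg_depletion Fraction of background CG dinucleotides rewritten
#'   to TG (methylation-driven CpG loss); island blocks are untouched.
#' @param n_genes Named counts per class (housekeeping,
#'   developmental_TF, tissue_specific, other).
#' @param promoter Per-class promoter block: width (bp) and GC fraction;
#'   NULL = plain background.
#' @param gene_body_bp Gene body length.
#' @param min_gene_gap_bp Minimum spacing between gene anchors.
#' @param beta Coupling of window GC fraction to nucleosome sampling
#'   weight (weight ~ exp(beta * gc)).
#' @param gamma Input-library GC bias (weight ~ exp(gamma * gc)).
#' @param nuc_depth,input_depth Library sizes; the nucleosome library is
#'   deeper so the subsampling path is exercised.
#' @param p_unmeth_retained P(island unmethylated | overlaps retention).
#' @param p_unmeth_background P(island unmethylated | no overlap).
#' @param sperm_present_frac Fraction of genes with sperm mRNA present.
#' @param tissues Tissue names (10).
#' @param rpkm_threshold Expression threshold.
#' @param n_donors,present_min_donors Sperm presence-call geometry (13/7).
#' @param window_bp Analysis window width.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(
    chrom_lengths = c(chr1 = 2500000L, chr2 = 2500000L),
    background_gc = 0.40,
    cpg_depletion = 0.80,
    n_genes = c(housekeeping = 90L, developmental_TF = 60L,
                tissue_specific = 90L, other = 60L),
    promoter = list(
      housekeeping = list(width = 600L, gc = 0.65),
      developmental_TF = list(width = 4000L, gc = 0.60),
      tissue_specific = list(width = 600L, gc = 0.30),
      other = NULL),
    gene_body_bp = 2000L,
    min_gene_gap_bp = 9000L,
    beta = 4,
    gamma = 0.5,
    nuc_depth = 750000L,
    input_depth = 500000L,
    p_unmeth_retained = 0.86,
    p_unmeth_background = 0.48,
    sperm_present_frac = 0.6,
    tissues = c("testes", "brain", "breast", "colon", "heart", "liver",
                "lymph_node", "skeletal_muscle", "adipose", "cerebellum"),
    rpkm_threshold = 0.5,
    n_donors = 13L,
    present_min_donors = 7L,
    window_bp = 150L) {
  cfg <- list(chrom_lengths = chrom_lengths, background_gc = background_gc,
              cpg_depletion = cpg_depletion, n_genes = n_genes,
              promoter = promoter, gene_body_bp = as.integer(gene_body_bp),
              min_gene_gap_bp = as.integer(min_gene_gap_bp),
              beta = beta, gamma = gamma,
              nuc_depth = as.integer(nuc_depth),
              input_depth = as.integer(input_depth),
              p_unmeth_retained = p_unmeth_retained,
              p_unmeth_background = p_unmeth_background,
              sperm_present_frac = sperm_present_frac,
              tissues = tissues, rpkm_threshold = rpkm_threshold,
              n_donors = as.integer(n_donors),
              present_min_donors = as.integer(present_min_donors),
              window_bp = as.integer(window_bp))
  if (any(chrom_lengths < 10000L)) stop("chromosome lengths must be >= 10 kb")
  pr <- c(cfg$p_unmeth_retained, cfg$p_unmeth_background,
          cfg$sperm_present_frac, cfg$background_gc, cfg$cpg_depletion)
  if (any(pr < 0 | pr > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$nuc_depth <= 0 || cfg$input_depth <= 0) stop("depths must be > 0")
  if (cfg$beta < 0 || cfg$gamma < 0) stop("beta/gamma must be >= 0")
  if (!setequal(names(cfg$n_genes),
                c("housekeeping", "developmental_TF", "tissue_specific",
                  "other")))
    stop("n_genes must name the four gene classes")
  class(cfg) <- "synthetic_config"
  cfg
}

# iid sequence with P(C)=P(G)=gc/2, P(A)=P(T)=(1-gc)/2 (obs/exp CpG ~ 1)
.random_seq <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate a synthetic genome with class-specific promoter architecture
#'
#' Background bases are drawn iid at the configured GC fraction; a
#' configured fraction of background CG dinucleotides is rewritten to TG
#' (deamination-style CpG depletion).  Gene anchors are placed with a
#' minimum spacing, then each gene's promoter block (class-specific width
#' and GC) is written centered on its TSS, overwriting the depleted
#' background, so planted islands keep obs/exp CpG ~ 1.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; the output is a pure function of
#'   (config, seed).
#' @return List: `genome` (DNAStringSet), `genes` (data.frame gene_id,
#'   chrom, strand, tss, tes, class, prom_start, prom_end; 0-based),
#'   `transcripts` (gene_id, tss), `go` (gene_id, term_id, term_name).
#' @export
generate_genome <- function(config = synthetic_config(), seed = 1L) {
  with_seed(seed, {
    ntot <- sum(config$n_genes)
    lens <- config$chrom_lengths
    # genes per chromosome, proportional to length
    per <- diff(round(ntot * cumsum(c(0, lens)) / sum(lens)))
    names(per) <- names(lens)
    margin <- 4200L
    gap <- config$min_gene_gap_bp
    chrom <- character(0)
    anchor <- integer(0)
    for (ch in names(lens)) {
      n <- per[[ch]]
      if (n == 0L) next
      lo <- margin
      hi <- lens[[ch]] - margin
      slack <- (hi - lo) - (n - 1) * gap
      if (slack <= 0) stop("genes do not fit: enlarge genome or reduce genes")
      u <- sort(stats::runif(n, 0, slack))
      pos <- as.integer(round(lo + u + (seq_len(n) - 1L) * gap))
      chrom <- c(chrom, rep(ch, n))
      anchor <- c(anchor, pos)
    }
    cls <- sample(rep(names(config$n_genes), config$n_genes))
    strand <- sample(c("+", "-"), ntot, replace = TRUE)
    tss <- anchor
    tes <- ifelse(strand == "+", tss + config$gene_body_bp,
                  tss - config$gene_body_bp)
    genes <- data.frame(
      gene_id = sprintf("g%04d", seq_len(ntot)),
      chrom = chrom, strand = strand, tss = tss, tes = as.integer(tes),
      class = cls, stringsAsFactors = FALSE)
    # chromosome sequences: background + CpG depletion, then blocks
    seqs <- lapply(names(lens), function(ch) {
      b <- .random_seq(lens[[ch]], config$background_gc)
      cg <- which(b[-length(b)] == "C" & b[-1L] == "G")
      hit <- cg[stats::runif(length(cg)) < config$cpg_depletion]
      b[hit] <- "T" # CG -> TG
      b
    })
    names(seqs) <- names(lens)
    genes$prom_start <- rep(NA_integer_, ntot)
    genes$prom_end <- rep(NA_integer_, ntot)
    for (i in seq_len(ntot)) {
      p <- config$promoter[[genes$class[i]]]
      if (is.null(p)) next
      half <- p$width %/% 2L
      a <- genes$tss[i] - half # 0-based start
      b <- a + p$width         # 0-based end (half-open)
      seqs[[genes$chrom[i]]][(a + 1L):b] <- .random_seq(p$width, p$gc)
      genes$prom_start[i] <- a
      genes$prom_end[i] <- b
    }
    genome <- Biostrings::DNAStringSet(
      vapply(seqs, paste, character(1), collapse = ""))
    # transcripts: canonical TSS + occasional downstream alternate
    alt <- stats::runif(ntot) < 0.3
    off <- sample(20:150, ntot, replace = TRUE) *
      ifelse(genes$strand == "+", 1L, -1L)
    transcripts <- rbind(
      data.frame(gene_id = genes$gene_id, tss = genes$tss),
      data.frame(gene_id = genes$gene_id[alt],
                 tss = as.integer(genes$tss[alt] + off[alt])))
    # flat GO labels: the devTF rule needs both tags; decoys carry one
    dev <- genes$gene_id[genes$class == "developmental_TF"]
    other <- genes$gene_id[genes$class == "other"]
    tsg <- genes$gene_id[genes$class == "tissue_specific"]
    go_rows <- function(ids, id, name)
      data.frame(gene_id = ids, term_id = rep(id, length(ids)),
                 term_name = rep(name, length(ids)))
    go <- rbind(
      go_rows(dev, "GO:0006355",
              "regulation of transcription, DNA-dependent"),
      go_rows(dev, "GO:0009790", "embryo development"),
      go_rows(head(other, max(1L, length(other) %/% 5L)), "GO:0006355",
              "regulation of transcription, DNA-dependent"),
      go_rows(head(tsg, max(1L, length(tsg) %/% 10L)), "GO:0048513",
              "animal organ development"))
    list(genome = genome, genes = genes, transcripts = transcripts, go = go)
  })
}

#' Simulate nucleosome-fraction and input reads with GC coupling
#'
#' Per-window sampling weights are exp(beta * gc_fraction) for the
#' nucleosome library and exp(gamma * gc_fraction) for the input
#' (gamma << beta).  Window counts are multinomial at the configured
#' depths; centers are uniform within the window, then converted to
#' 5'-end records at center -/+ shift with random strand; records whose
#' 5' end falls off the chromosome are dropped.
#'
#' @param genome A `DNAStringSet`.
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @param shift_bp Center-to-5' shift (default 75).
#' @return List with `nuc` and `input` read data.frames (chrom, pos,
#'   strand) and the true `nuc_centers`/`input_centers` vectors.
#' @export
simulate_reads <- function(genome, config = synthetic_config(), seed = 1L,
                           shift_bp = 75L) {
  grid <- make_windows(genome, config$window_bp)
  comp <- window_base_counts(genome, grid)
  gcf <- comp$gc / grid$width
  wch <- window_chroms(grid)
  wst <- window_starts(grid)
  draw <- function(bias, depth, sd) {
    with_seed(sd, {
      w <- exp(bias * gcf)
      if (sum(w) <= 0) stop("zero total sampling weight")
      cnt <- as.vector(stats::rmultinom(1, depth, w))
      win <- rep.int(seq_along(cnt), cnt)
      center <- wst[win] + sample.int(grid$width, depth, replace = TRUE) - 1L
      strand <- sample(c("+", "-"), depth, replace = TRUE)
      pos <- as.integer(center + ifelse(strand == "+", -shift_bp, shift_bp))
      chrom <- wch[win]
      ok <- pos >= 0L & pos < grid$seqlengths[chrom]
      list(reads = data.frame(chrom = chrom[ok], pos = pos[ok],
                              strand = strand[ok]),
           centers = center[ok])
    })
  }
  nuc <- draw(config$beta, config$nuc_depth, seed)
  inp <- draw(config$gamma, config$input_depth, seed + 1L)
  list(nuc = nuc$reads, input = inp$reads,
       nuc_centers = nuc$centers, input_centers = inp$centers)
}

#' Simulate methylation labels, expression matrix, and presence calls
#'
#' Island methylation is Bernoulli given retention overlap (configured
#' conditional probabilities); the RPKM matrix places housekeeping genes
#' at/above threshold in all tissues and tissue-specific genes in exactly
#' one; presence calls make a configurable fraction of genes
#' sperm-present (>= 7 of 13 donors).
#'
#' @param islands `GRanges` of CpG islands.
#' @param regions `GRanges` of retention regions.
#' @param genes Gene data.frame with a `class` column.
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return List: `islands` (input islands with a `methylation` column),
#'   `rpkm` (genes x tissues matrix), `presence` (genes x donors logical
#'   matrix).
#' @export
simulate_labels <- function(islands, regions, genes,
                            config = synthetic_config(), seed = 1L) {
  with_seed(seed, {
    ov <- GenomicRanges::countOverlaps(islands, regions) > 0
    p <- ifelse(ov, config$p_unmeth_retained, config$p_unmeth_background)
    unmeth <- stats::runif(length(islands)) < p
    S4Vectors::mcols(islands)$methylation <-
      ifelse(unmeth, "unmethylated", "methylated")
    nt <- length(config$tissues)
    ng <- nrow(genes)
    thr <- config$rpkm_threshold
    rpkm <- matrix(stats::runif(ng * nt, 0, thr * 0.9), nrow = ng,
                   dimnames = list(genes$gene_id, config$tissues))
    expr_in <- function(i, cols) {
      rpkm[i, cols] <<- thr + stats::rlnorm(length(cols), meanlog = 1, sdlog = 1)
    }
    for (i in seq_len(ng)) {
      cl <- genes$class[i]
      if (cl == "housekeeping") expr_in(i, seq_len(nt))
      else if (cl == "tissue_specific") expr_in(i, sample.int(nt, 1L))
      else if (cl == "developmental_TF") expr_in(i, sample.int(nt, sample(2:9, 1L)))
      else expr_in(i, sample.int(nt, sample(2:9, 1L)))
    }
    present <- stats::runif(ng) < config$sperm_present_frac
    k <- ifelse(present,
                sample(config$present_min_donors:config$n_donors, ng,
                       replace = TRUE),
                sample(0:(config$present_min_donors - 1L), ng,
                       replace = TRUE))
    calls <- matrix(FALSE, ng, config$n_donors,
                    dimnames = list(genes$gene_id,
                                    paste0("donor", seq_len(config$n_donors))))
    for (i in seq_len(ng))
      if (k[i] > 0L) calls[i, sample.int(config$n_donors, k[i])] <- TRUE
    list(islands = islands, rpkm = rpkm, presence = calls)
  })
}
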