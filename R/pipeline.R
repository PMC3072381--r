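# End-to-end orchestration: simulate -> compose -> score -> regions ->
# classify -> evaluate -> profiles, with per-stage filter accounting so
# every denominator is auditable.

#' Run the full synthetic pipeline
#'
#' Generates a genome and reads from the synthetic model, builds the
#' composition/uniqueness tracks and CpG islands, depth-matches the
#' nucleosome library by subsampling, scores windows, calls enrichment
#' regions, evaluates GC/CpG as retention classifiers (ROC + CpG-island
#' operating point), links island methylation to retention, runs the
#' expression-breadth trend test, and computes class meta-profiles.
#'
#' ROC labels are "window overlaps a called enrichment region".  When the
#' caller (correctly) returns no regions - e.g. the null generator with
#' beta = gamma = 0 - the ROC falls back to the sign of the retention
#' score as the label, recorded in `report$roc$label_source`.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param params A [retention_params()].
#' @param outdir Optional directory; when given, FASTA/BED/TSV outputs
#'   and the resolved configuration are written there.
#' @return A report list: `counts` (per-stage record/filter counts),
#'   `roc` (auc_gc, auc_cpg, label_source, island operating point),
#'   `methylation` (table, precision, recall, chi2, p), `trend` (table,
#'   chi2, p), `classes` (per-class TSS retention), `profiles` (per-class
#'   meta-profiles of GC and retention score), plus the intermediate
#'   objects needed to audit them.
#' @export
run_pipeline <- function(config = synthetic_config(), seed = 1L,
                         params = retention_params(), outdir = NULL) {
  seeds <- with_seed(seed, sample.int(1000000L, 6L))
  ## simulate
  sim <- generate_genome(config, seeds[1])
  reads <- simulate_reads(sim$genome, config, seeds[2],
                          shift_bp = params$shift_bp)
  ## compose
  grid <- make_windows(sim$genome, params$window_bp)
  comp <- window_base_counts(sim$genome, grid)
  comp$unique20 <- kmer_uniqueness_mask(sim$genome, grid)
  islands <- detect_cpg_islands(sim$genome)
  ## score (depth-match the deeper nucleosome library first)
  n_nuc <- nrow(reads$nuc)
  n_inp <- nrow(reads$input)
  nuc_use <- if (n_nuc > n_inp)
    subsample_reads(reads$nuc, n_inp, seeds[3]) else reads$nuc
  nuc_cnt <- center_counts(nuc_use, grid, params$shift_bp)
  inp_cnt <- center_counts(reads$input, grid, params$shift_bp)
  excl <- !comp$unique20 | comp$n > 0L
  track <- retention_score_track(nuc_cnt, inp_cnt,
                                 min_total = params$min_total_reads,
                                 excluded = excl)
  ## regions
  regions <- call_enriched_regions(reads$nuc, reads$input,
                                   grid$seqlengths, params)
  ## evaluate: ROC of GC/CpG vs retention
  keep <- track$keep
  ov <- GenomicRanges::countOverlaps(grid_ranges(grid), regions) > 0
  if (any(ov[keep]) && !all(ov[keep])) {
    lab <- ov
    label_source <- "regions"
  } else {
    lab <- !is.na(track$score) & track$score > 0
    label_source <- "score_sign"
  }
  roc_gc <- roc_auc(comp$gc[keep], lab[keep])
  roc_cpg <- roc_auc(comp$cpg[keep], lab[keep])
  in_island <- GenomicRanges::countOverlaps(grid_ranges(grid), islands) > 0
  island_point <- tryCatch(binary_predictor_point(in_island[keep], lab[keep]),
                           error = function(e) c(sensitivity = NA_real_,
                                                 specificity = NA_real_))
  ## labels: methylation, expression, presence
  labs <- simulate_labels(islands, regions, sim$genes, config, seeds[4])
  meth <- tryCatch(methylation_overlap_stats(labs$islands, regions),
                   error = function(e) NULL)
  meth_chi <- if (!is.null(meth) && all(rowSums(meth$table) > 0) &&
                  all(colSums(meth$table) > 0))
    chisq_independence(meth$table) else list(chi2 = NA_real_, p = NA_real_)
  ## gene classes and trend over expression breadth
  classes <- classify_genes(labs$rpkm, sim$go,
                            threshold = config$rpkm_threshold)
  retained <- tss_retained(sim$genes, regions, sim$transcripts)
  br <- classes$breadth[match(sim$genes$gene_id, classes$gene_id)]
  tt <- data.frame(score = sort(unique(br)))
  tt$total <- as.integer(table(factor(br, levels = tt$score)))
  tt$successes <- as.integer(tapply(retained,
                                    factor(br, levels = tt$score), sum))
  tt$successes[is.na(tt$successes)] <- 0L
  trend <- if (nrow(tt) >= 2) cochran_armitage_trend(tt) else
    list(chi2 = NA_real_, p = NA_real_)
  class_ret <- vapply(split(retained, sim$genes$class), mean, numeric(1))
  ## profiles per class (GC fraction and retention score)
  prof <- lapply(split(sim$genes, sim$genes$class), function(g) {
    anch <- data.frame(chrom = g$chrom, pos = g$tss, strand = g$strand)
    list(gc = meta_profile(comp$gc / grid$width, grid, anch),
         score = meta_profile(track$score, grid, anch, mask = track$keep))
  })
  counts <- list(
    n_genes = nrow(sim$genes), n_windows = grid$n,
    n_islands = length(islands),
    n_reads_nuc = n_nuc, n_reads_input = n_inp,
    n_reads_nuc_used = nrow(nuc_use),
    n_windows_nonunique = sum(!comp$unique20),
    n_windows_with_N = sum(comp$n > 0L),
    n_windows_low_coverage = sum(track$low_coverage),
    n_windows_kept = sum(keep),
    n_regions = length(regions))
  report <- list(
    seed = seed, counts = counts,
    roc = list(auc_gc = roc_gc$auc, auc_cpg = roc_cpg$auc,
               label_source = label_source, island_point = island_point),
    methylation = if (is.null(meth)) NULL else
      c(meth, list(chi2 = meth_chi$chi2, p = meth_chi$p)),
    trend = list(table = tt, chi2 = trend$chi2, p = trend$p),
    classes = list(tss_retention_rate = class_ret),
    profiles = prof,
    objects = list(grid = grid, comp = comp, islands = islands,
                   regions = regions, track = track, genes = sim$genes,
                   transcripts = sim$transcripts, go = sim$go,
                   rpkm = labs$rpkm, presence = labs$presence,
                   islands_labeled = labs$islands,
                   roc_gc = roc_gc, roc_cpg = roc_cpg))
  if (!is.null(outdir)) write_pipeline_outputs(report, sim, outdir, config)
  report
}

# write the standard text outputs of a pipeline run
write_pipeline_outputs <- function(report, sim, outdir, config) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  o <- report$objects
  write_genome_fasta(sim$genome, file.path(outdir, "genome.fa"))
  write_genes_tsv(sim$genes, file.path(outdir, "genes.tsv"))
  write_window_tsv(o$grid,
                   list(gc = o$comp$gc, cpg = o$comp$cpg, n = o$comp$n,
                        unique = as.integer(o$comp$unique20),
                        score = o$track$score,
                        keep = as.integer(o$track$keep)),
                   file.path(outdir, "window_tracks.tsv"))
  write_bed(o$regions, file.path(outdir, "regions.bed"),
            score_col = "enrichment_score")
  write_bed(o$islands, file.path(outdir, "cpg_islands.bed"))
  utils::write.table(report$trend$table, file.path(outdir, "trend_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(o$roc_gc$points, file.path(outdir, "roc_gc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(o$rpkm, file.path(outdir, "expression_rpkm.tsv"))
  cfg <- config
  cfg$promoter <- NULL
  jsonlite::write_json(
    c(list(seed = report$seed), cfg[!vapply(cfg, is.null, TRUE)]),
    file.path(outdir, "run_config.json"), auto_unbox = TRUE, digits = NA)
  headline <- list(
    auc_gc = report$roc$auc_gc, auc_cpg = report$roc$auc_cpg,
    label_source = report$roc$label_source,
    precision = report$methylation$precision,
    recall = report$methylation$recall,
    trend_chi2 = report$trend$chi2,
    counts = report$counts)
  jsonlite::write_json(headline, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
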