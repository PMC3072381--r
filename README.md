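# nucretain

Window-level analysis of nucleosome retention in mature human sperm and
its prediction from fine-scale base composition.

Most of the sperm genome swaps histones for protamines; the nucleosomes
that remain mark the loci whose chromatin state a father can pass to
the zygote. This package implements, as a tested pipeline, the analysis
showing that GC and CpG content of 150-bp windows predict where
nucleosomes are retained (MNase-seq vs genomic input), that retention
concentrates at the CpG-island promoters of broadly expressed genes and
developmental regulators, and that island retention in sperm is
associated with CpG islands that stay DNA-methylation-free in the early
embryo. It is aimed at epigenomics analysts who want the individual
statistics as reusable functions, plus a synthetic-genome generator so
the whole pipeline is testable without any external download.

## What it computes

* **Composition tracks** — per-window GC, within-window CpG and N
  counts; a 20-mer uniqueness (mappability-proxy) mask; CpG islands by
  the classical definition (≥ 200 bp, GC ≥ 0.5, obs/exp CpG ≥ 0.6).
* **Retention scoring** — 5′-end reads shifted 75 bp to fragment
  centers, counted in 150-bp windows; depth-matching subsampling; the
  normalized retention score *S* = (n − i)/√(n + i); a ≥ 5-read filter;
  a binomial/Benjamini–Hochberg enrichment-region caller (300-bp
  sliding windows); binomial −log10 tail scores for modified
  nucleosomes.
* **Gene-level statistics** — expression breadth (RPKM ≥ 0.5 in 10
  tissues), housekeeping / tissue-specific / developmental-TF classes,
  retained-at-TSS calls (within 50 bp), region location labels
  (TSS/TES/other genic/non-genic), 7-of-13-donor sperm mRNA presence,
  distal-site filtering (≥ 1 kb from genes).
* **Evaluation** — tie-aware ROC/AUC, sensitivity/specificity points,
  2×2 chi-square, the Cochran–Armitage trend test, stratified window
  correlations, and CpG-island methylation vs retention precision /
  recall.
* **Profiles** — TSS-anchored, strand-flipped 27 × 150-bp
  meta-profiles and clustered per-gene heat-map matrices.
* **Synthetic data** — seeded generator of a genome with class-specific
  promoter architecture, GC-coupled nucleosome reads (weight ∝
  e^(β·GC)), mildly GC-biased input reads, a 10-tissue RPKM matrix,
  13-donor presence calls, and retention-linked methylation labels.

## Worked example

A desk check first: the published 11-bin table of TSS retention by
expression breadth reproduces its printed trend statistic.

```r
library(nucretain)
tab <- data.frame(score = 0:10,
  total     = c(792, 1472, 835, 742, 653, 562, 617, 657, 817, 1248, 7502),
  successes = c(125,  313, 284, 316, 264, 251, 287, 324, 433,  711, 4555))
cochran_armitage_trend(tab)$chi2
#> 1303.692           # printed value: 1,303.7
```

Then a small end-to-end synthetic run (1 Mb, 60 genes, ~8 s):

```r
cfg <- synthetic_config(
  chrom_lengths = c(chr1 = 500000L, chr2 = 500000L),
  n_genes = c(housekeeping = 18L, developmental_TF = 12L,
              tissue_specific = 18L, other = 12L),
  nuc_depth = 150000L, input_depth = 100000L)
rep <- run_pipeline(cfg, seed = 1)

rep$counts$n_regions          # 61 enrichment regions called
rep$roc$auc_gc                # 0.973  GC ranks retained windows
rep$roc$auc_cpg               # 0.962  CpG count does almost as well
rep$roc$island_point          # sensitivity 0.945, specificity 0.985
rep$methylation$table
#>              retained not_retained
#> unmethylated       23            0
#> methylated          7            0
rep$trend$chi2                # 30.6   retention rises with breadth
rep$classes$tss_retention_rate
#> developmental_TF housekeeping other tissue_specific
#>                1            1     0               0
```

The AUCs say a random retained window outranks a random non-retained
one by GC content ~97% of the time — the synthetic analogue of the
published genome-wide 0.89. GC-rich housekeeping and developmental-TF
promoters are retained, AT-rich tissue-specific promoters are not, and
retained islands are predominantly the unmethylated ones (here all 30
islands overlap regions, so recall is 1 and precision reflects the
configured 0.86 concordance at small n).

There is also a file-based CLI:

```sh
inst/cli/nucretain simulate --outdir run1 --seed 2
inst/cli/nucretain score --nuc run1/reads_nuc.tsv \
    --input run1/reads_input.tsv --fasta run1/genome.fa \
    --out run1/scores.tsv
inst/cli/nucretain run-all --outdir run2 --seed 2
```

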