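---
title: "Predicting sperm nucleosome retention from base composition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting sperm nucleosome retention from base composition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucretain)
```

## The biological question

During spermatogenesis most of the genome exchanges histones for
protamines; a small fraction of nucleosomes is retained in mature sperm,
and where they are retained matters for what chromatin states a father
can transmit to the zygote. `nucretain` implements a window-level
analysis of the hypothesis that fine-scale base composition — GC content
and CpG density in 150-bp windows — is by itself an excellent predictor
of where nucleosomes are retained, and that retention at CpG islands in
sperm is linked to which islands stay free of DNA methylation in the
early embryo.

## The model and its statistics

**Window grid.** Each chromosome is tiled from position 0 into
non-overlapping 150-bp windows; a trailing partial window is dropped.
All internal window arithmetic is 0-based half-open; `GRanges` objects
(1-based closed) are used for interval sets, with conversion confined to
the I/O layer (BED files are 0-based half-open on disk).

**Retention score.** MNase-seq reads are recorded as 5′ ends with
strand. Each read is shifted 75 bp in the direction of sequencing
(half the mononucleosome fragment length), turning end counts into
fragment-center counts per window. Because the nucleosome library is
deeper than the genomic input, it is first subsampled (uniformly,
without replacement, seeded) to input depth. The normalized retention
score of a window is

$$S = \frac{n - i}{\sqrt{n + i}}$$

with $n$ nucleosome and $i$ input centers. Windows with $n + i < 5$,
windows containing N, and windows containing any 20-mer that occurs more
than once in the genome (counting both strands — a mappability proxy)
are excluded from correlation/ROC analyses.

**Region calling.** Enrichment regions are called with a 300-bp window
sliding at 150-bp steps: a one-sided binomial test of $n$ against
$n + i$ with success probability equal to the nucleosome depth fraction,
Benjamini–Hochberg correction at $\alpha = 0.05$, merging of overlapping
significant windows, and a region score equal to the maximum
$-\log_{10}(\text{adjusted } p)$ of its windows. The published analysis
delegated this step to an external peak caller; the binomial/BH choice
here is the simplest faithful equivalent and every constant is
configurable through `retention_params()`.

**Classification metrics.** `roc_auc()` ranks windows by decreasing
GC (or CpG) count with one threshold per distinct value — ties are
massive for integer counts, and grouping them is equivalent to the
half-credit pair convention, so the trapezoidal area equals
$P(\text{score}^+ > \text{score}^-) + \tfrac12 P(\text{tie})$, computed
through the rank identity. CpG islands as a binary predictor are
summarized by a single sensitivity/specificity point.

**CpG islands.** The classical composition definition: maximal
intervals of length ≥ 200 bp with GC ≥ 0.5 and observed/expected CpG
$(\#CpG \cdot L)/(\#C \cdot \#G) \ge 0.6$. Qualifying 200-bp seeds are
merged greedily left-to-right while the merged interval still satisfies
all three thresholds, which resolves the algorithmic ambiguity the
verbal definition leaves open and guarantees that every reported island
re-satisfies the thresholds when recomputed. A consequence worth
knowing: a qualifying seed may straddle an island/background boundary,
so detected islands can extend up to ~100 bp into AT-rich flanks, and a
GC-rich block shorter than 200 bp can still seed a 200-bp island if its
immediate context keeps the window above the thresholds. Only a
sequence with no qualifying 200-bp window at all yields no island.

**Gene classes and trend tests.** Expression breadth is the number of
tissues (of 10) with RPKM ≥ 0.5 (inclusive). Housekeeping genes come
from an external list when supplied, else breadth = 10; tissue-specific
means breadth = 1; developmental transcription factors are genes
annotated with GO:0006355 *and* any GO term whose name contains
"development". Sperm mRNA presence means detection in ≥ 7 of 13 donors.
A gene is "retained at the TSS" when any transcript start site lies
within 50 bp of a region boundary (inside = 0; inclusive at 50). The
trend of retention across ordered bins is tested with the
Cochran–Armitage 1-df chi-square score test; bin scores default to
0..k−1, which is immaterial because the statistic is affine-invariant in
the scores (verified to 1e-8 relative in the suite).

**Meta-profiles.** 4,000 bp is not divisible by 150, so profiles use 27
bins (4,050 bp) centered on the anchor-containing window; minus-strand
anchors are flipped so positive offsets point downstream of
transcription. Heat-map row ordering clusters the companion GC matrix
(Euclidean distance, average linkage) and reuses that leaf order for the
retention matrix; `stats::hclust`'s native leaf order is deterministic,
so no bespoke tie-breaking traversal is layered on top.

## The synthetic stated world

The generator exists so every stage is testable without downloads; its
defaults are fixed once and are not tuned to test outcomes.

* Genome: 2 × 2.5 Mb, background GC 0.40; 80% of background CG
  dinucleotides rewritten to TG, emulating methylation-driven CpG
  depletion, so background obs/exp CpG sits near 0.2.
* Genes: 300 non-overlapping (90 housekeeping, 60 developmental TF,
  90 tissue-specific, 60 other), ≥ 9 kb apart. Housekeeping TSSs carry
  sharp 600-bp islands (GC 0.65), developmental TFs broad 4-kb GC-rich
  domains (GC 0.60), tissue-specific promoters are AT-rich (GC 0.30).
  Island blocks are drawn iid, which makes their obs/exp CpG ≈ 1.
* Reads: per-window sampling weight $\propto e^{\beta \cdot GC}$ with
  β = 4 for the nucleosome fraction and $\propto e^{\gamma \cdot GC}$
  with γ = 0.5 for the input (a mild sequencing GC bias); depths
  750k/500k so the depth-matching subsampling path is always exercised.
* Labels: island methylation is Bernoulli given retention overlap with
  P(unmethylated | retained) = 0.86 and P(unmethylated | background) =
  0.48 — the second value back-computed from the published margins
  (3,973 unmethylated among 8,326 non-overlapping islands). The RPKM
  matrix gives housekeeping genes ≥ 0.5 everywhere and tissue-specific
  genes exactly one expressed tissue; presence calls make ~60% of genes
  sperm-present.

What a green synthetic run does **not** establish: the generator has no
repeats (the uniqueness mask is near-trivially true), no
fragment-length variation, no nucleosome positioning periodicity, no
sequencing errors, and iid base composition rather than isochore
structure. It validates the pipeline's plumbing and the direction and
rough magnitude of every statistic, not genome-realistic effect sizes.

## Numerical and degenerate-input choices

* Score undefined at $n + i = 0$: an error for the scalar function, an
  `NA` plus flags in the track constructor; callers filter first.
* Binomial scores are computed on the log scale (`pbinom(log.p=)`), so
  deep enrichment never underflows to `Inf`.
* k-mers are 2-bit packed into doubles via a linear-filter rolling
  encoding — exact up to k = 26 (4^26 < 2^53) — and multiplicity comes
  from a two-sided `duplicated()` pass; k-mers containing N count as
  non-unique.
* The region caller refuses zero input depth; an empty significant set
  returns an empty `GRanges` rather than an error.
* Under the complete null (β = γ = 0) the BH-controlled caller returns
  zero regions for ~95% of seeds — correctly. Since region-overlap ROC
  labels are then undefined, `run_pipeline()` falls back to
  sign-of-retention-score labels and records `label_source =
  "score_sign"` in the report; the null acceptance band (AUC 0.5 ± 0.02)
  is checked on that fallback. The null uses γ = 0 as well: with γ > 0
  the input GC bias makes the score anti-correlated with GC, which is a
  different (and wrong) null hypothesis for "GC decoupled from reads".
* `subsample_reads()` and all generator stages run under a private RNG
  state; the caller's `.Random.seed` is saved and restored.

## Known limitations

The modified-nucleosome (H3K4me3/H3K27me3) score implements a declared
formula — upper binomial tail against the input at the depth ratio —
because the source analysis names only "a score based on the binomial
distribution". The region caller is a deliberately simple stand-in for
the published external tool; absolute region counts are therefore not
comparable to published counts, and acceptance checks use desk-
reproducible legend tables plus property-based bounds instead.
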