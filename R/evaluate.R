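# ROC/AUC for window-level predictors, single-point binary classifiers,
# contingency statistics, the Cochran-Armitage trend test, and
# (stratified) window-track correlations.

#' ROC curve and AUC for a numeric score against binary labels
#'
#' The curve sweeps one threshold per distinct score value (ties are
#' grouped: integer GC counts make ties massive), accumulating true- and
#' false-positive rates in decreasing score order.  The AUC is the
#' trapezoidal area, computed through the rank (Mann-Whitney) identity,
#' which equals P(score+ > score-) + 1/2 P(tie).
#'
#' @param scores Numeric predictor, higher = more positive.
#' @param labels Logical (or 0/1) ground truth.
#' @return A `roc_result`: list with `points` (data.frame fpr, tpr from
#'   (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  np <- sum(labels)
  nn <- sum(!labels)
  if (np == 0L || nn == 0L)
    stop("undefined AUC: labels contain a single class")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
  o <- order(scores, decreasing = TRUE)
  ss <- scores[o]
  ls <- labels[o]
  last <- cumsum(rle(ss)$lengths)
  ctp <- cumsum(ls)
  cfp <- cumsum(!ls)
  pts <- data.frame(fpr = c(0, cfp[last] / nn), tpr = c(0, ctp[last] / np))
  structure(list(points = pts, auc = unname(auc)), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC over", nrow(x$points) - 1L, "threshold(s); AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Sensitivity/specificity of a binary predictor
#'
#' @param predictor Logical prediction per item.
#' @param labels Logical ground truth.
#' @return Named numeric vector c(sensitivity, specificity).
#' @export
binary_predictor_point <- function(predictor, labels) {
  predictor <- as.logical(predictor)
  labels <- as.logical(labels)
  tp <- sum(predictor & labels)
  fn <- sum(!predictor & labels)
  tn <- sum(!predictor & !labels)
  fp <- sum(predictor & !labels)
  if (tp + fn == 0L || tn + fp == 0L)
    stop("undefined rate: labels contain a single class")
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' CpG-island methylation vs retention overlap statistics
#'
#' Cross-classifies islands by methylation label and by >= 1 bp overlap
#' with any retention region; reports precision (unmethylated fraction of
#' retained islands) and recall (retained fraction of unmethylated
#' islands).
#'
#' @param islands `GRanges` with a metadata column `methylation` taking
#'   values "unmethylated"/"methylated" (or a logical `unmethylated`).
#' @param regions `GRanges` of retention regions.
#' @return List with `table` (2x2 integer matrix, rows unmethylated/
#'   methylated, columns retained/not_retained), `precision`, `recall`.
#' @export
methylation_overlap_stats <- function(islands, regions) {
  if (length(islands) == 0L) stop("empty island set")
  mc <- S4Vectors::mcols(islands)
  if (!is.null(mc$unmethylated)) {
    unmeth <- as.logical(mc$unmethylated)
  } else if (!is.null(mc$methylation)) {
    if (!all(mc$methylation %in% c("methylated", "unmethylated")))
      stop("methylation labels must be 'methylated'/'unmethylated'")
    unmeth <- mc$methylation == "unmethylated"
  } else stop("islands need a 'methylation' or 'unmethylated' column")
  ov <- suppressWarnings(GenomicRanges::countOverlaps(islands, regions)) > 0
  tab <- matrix(c(sum(unmeth & ov), sum(unmeth & !ov),
                  sum(!unmeth & ov), sum(!unmeth & !ov)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("unmethylated", "methylated"),
                                c("retained", "not_retained")))
  if (sum(tab[, "retained"]) == 0L)
    stop("no island overlaps any region: precision undefined")
  list(table = tab,
       precision = tab["unmethylated", "retained"] / sum(tab[, "retained"]),
       recall = tab["unmethylated", "retained"] / sum(tab["unmethylated", ]))
}

#' Cochran-Armitage chi-square test for trend in proportions
#'
#' One-degree-of-freedom score test for a linear trend of success
#' proportions across ordered bins:
#' chi2 = T^2 / V with T = sum(r_i s_i) - pbar sum(n_i s_i) and
#' V = pbar (1 - pbar) (sum(n_i s_i^2) - (sum(n_i s_i))^2 / N);
#' invariant under affine transformation of the scores.
#'
#' @param totals Integer vector of bin totals (or a data.frame with
#'   columns total, successes and optionally score).
#' @param successes Integer vector of bin successes.
#' @param scores Bin scores; default 0..k-1.
#' @return List with `chi2`, `p` (chi-square(1) upper tail), `df = 1`.
#' @export
cochran_armitage_trend <- function(totals, successes = NULL, scores = NULL) {
  if (is.data.frame(totals)) {
    tab <- totals
    if (is.null(scores)) scores <- tab$score
    successes <- tab$successes
    totals <- tab$total
  }
  k <- length(totals)
  if (k < 2L) stop("need at least two bins")
  if (is.null(scores)) scores <- seq_len(k) - 1
  if (length(successes) != k || length(scores) != k) stop("length mismatch")
  if (any(successes < 0) || any(successes > totals))
    stop("successes must lie in 0..total per bin")
  N <- sum(totals)
  R <- sum(successes)
  pbar <- R / N
  Tn <- sum(successes * scores) - pbar * sum(totals * scores)
  V <- pbar * (1 - pbar) *
    (sum(totals * scores^2) - sum(totals * scores)^2 / N)
  if (!is.finite(V) || V <= 0) return(list(chi2 = 0, p = 1, df = 1L))
  chi2 <- Tn^2 / V
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Chi-square test of independence for a contingency table
#'
#' @param table Integer matrix (2x2 or larger).
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return List with `chi2`, `p`, `df`.
#' @export
chisq_independence <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin in contingency table")
  N <- sum(table)
  expd <- outer(rs, cs) / N
  dev <- abs(table - expd)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expd)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = df, lower.tail = FALSE),
       df = df)
}

#' Pearson correlation of two window tracks, optionally stratified
#'
#' Windows excluded by the shared mask are dropped.  With `stratify_by`
#' (e.g. GC count), one correlation per stratum is returned with a 95%
#' Fisher-z confidence interval; strata with fewer than `min_n` windows
#' are flagged as skipped.
#'
#' @param a,b Numeric per-window tracks of equal length.
#' @param mask Optional logical keep vector.
#' @param stratify_by Optional integer per-window stratum.
#' @param min_n Minimum windows per stratum (default 3).
#' @return Without strata, a single correlation. With strata, a
#'   data.frame (stratum, n, r, ci_lo, ci_hi, skipped).
#' @export
window_track_correlation <- function(a, b, mask = NULL, stratify_by = NULL,
                                     min_n = 3L) {
  if (length(a) != length(b)) stop("tracks differ in length")
  keep <- !is.na(a) & !is.na(b)
  if (!is.null(mask)) keep <- keep & mask
  a <- a[keep]
  b <- b[keep]
  if (is.null(stratify_by)) {
    if (length(a) < 3L) stop("fewer than 3 windows after masking")
    return(stats::cor(a, b))
  }
  g <- stratify_by[keep]
  out <- lapply(sort(unique(g)), function(s) {
    i <- g == s
    n <- sum(i)
    if (n < min_n || stats::sd(a[i]) == 0 || stats::sd(b[i]) == 0)
      return(data.frame(stratum = s, n = n, r = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_, skipped = TRUE))
    r <- stats::cor(a[i], b[i])
    if (n > 3L && abs(r) < 1) {
      z <- atanh(r)
      se <- 1 / sqrt(n - 3)
      lo <- tanh(z - 1.96 * se)
      hi <- tanh(z + 1.96 * se)
    } else lo <- hi <- NA_real_
    data.frame(stratum = s, n = n, r = r, ci_lo = lo, ci_hi = hi,
               skipped = FALSE)
  })
  do.call(rbind, out)
}
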