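#' @include AllGenerics.R
NULL

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Computed as the Mann-Whitney pair statistic
#' P(score_pos > score_neg) + 0.5 P(tie), via midranks, so ties are handled
#' exactly. Returns `NA` (an undefined-marker, not an error) when only one
#' class is present.
#'
#' @param scores Numeric vector of predicted probabilities or scores.
#' @param labels Binary 0/1 vector.
#' @return AUROC in `[0, 1]`, or `NA` if labels are single-class.
#' @export
#' @examples
#' aurocScore(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)) # 0.75
aurocScore <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  npos <- sum(pos)
  nneg <- sum(!pos)
  if (npos == 0L || nneg == 0L) return(undefinedRate())
  r <- rank(scores)
  (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' F1-maximizing decision threshold
#'
#' Sweeps all observed unique scores as candidate thresholds under the
#' decision rule "predict positive iff score >= threshold" and returns the
#' threshold maximizing F1; ties are broken toward the smallest threshold.
#'
#' @inheritParams aurocScore
#' @return The selected threshold (one of the observed scores).
#' @export
#' @examples
#' f1OptimalThreshold(c(0.2, 0.6, 0.9), c(0, 1, 1)) # 0.6
f1OptimalThreshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1)
  if (npos == 0L) validationError("F1 undefined: no positive labels")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # last index of each distinct score value in the descending order: the
  # cumulative counts there are the confusion counts for threshold = value
  last <- cumsum(rle(s)$lengths)
  thr <- s[last]
  tpT <- tp[last]
  fpT <- fp[last]
  fnT <- npos - tpT
  f1 <- ifelse(tpT == 0, 0, 2 * tpT / (2 * tpT + fpT + fnT))
  best <- which(f1 == max(f1))
  # thr is descending; the largest qualifying index is the smallest threshold
  thr[max(best)]
}

#' Confusion-matrix rates at a threshold
#'
#' Counts TP/FP/TN/FN under the rule "score >= threshold is positive" and
#' returns TPR = TP/(TP+FN), TNR = TN/(TN+FP), FPR, FNR. Rates whose
#' conditioning class is empty are `NA` (undefined-markers), never 0.
#'
#' @inheritParams aurocScore
#' @param threshold Decision threshold in `[0, 1]` (or on the score scale).
#' @return Named list with `tp`, `fp`, `tn`, `fn`, `tpr`, `tnr`, `fpr`,
#'   `fnr`.
#' @export
confusionRates <- function(scores, labels, threshold) {
  stopifnot(length(scores) == length(labels), length(threshold) == 1L)
  predPos <- scores >= threshold
  tp <- sum(predPos & labels == 1)
  fn <- sum(!predPos & labels == 1)
  fp <- sum(predPos & labels == 0)
  tn <- sum(!predPos & labels == 0)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else undefinedRate()
  tnr <- if (tn + fp > 0) tn / (tn + fp) else undefinedRate()
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       tpr = tpr, tnr = tnr,
       fpr = if (is.na(tnr)) undefinedRate() else 1 - tnr,
       fnr = if (is.na(tpr)) undefinedRate() else 1 - tpr)
}

#' Expected calibration error
#'
#' Partitions `[0, 1]` into `nBins` equal-width bins (final bin
#' right-closed) and returns the bin-size-weighted mean absolute difference
#' between the mean predicted score (bin confidence) and the empirical
#' positive rate in each bin.
#'
#' @inheritParams aurocScore
#' @param nBins Number of equal-width bins (default 10).
#' @return ECE in `[0, 1]`.
#' @export
eceScore <- function(scores, labels, nBins = 10L) {
  stopifnot(nBins >= 1L)
  n <- length(scores)
  if (n == 0L) validationError("ECE undefined on empty input")
  bin <- pmin(floor(scores * nBins) + 1L, nBins)
  nb <- tabulate(bin, nbins = nBins)
  sumScore <- vapply(seq_len(nBins), function(b) sum(scores[bin == b]), numeric(1))
  sumPos <- vapply(seq_len(nBins), function(b) sum(labels[bin == b]), numeric(1))
  occ <- nb > 0
  sum(nb[occ] / n * abs(sumScore[occ] / nb[occ] - sumPos[occ] / nb[occ]))
}

resolveThreshold <- function(scores, labels, thresholdPolicy) {
  if (is.numeric(thresholdPolicy)) return(thresholdPolicy)
  if (identical(thresholdPolicy, "f1")) return(f1OptimalThreshold(scores, labels))
  validationError(sprintf("unknown threshold policy '%s'", thresholdPolicy))
}

#' Per-group performance and calibration table
#'
#' Computes, for every level of `attribute`, the group size, positive count,
#' TPR/TNR/FPR/FNR at a shared threshold, within-group AUROC and ECE. The
#' threshold is chosen once on the full (ungrouped) evaluation subset and
#' applied to all groups, so groups are compared at a common operating
#' point.
#'
#' @param pred A [PredictionSet-class].
#' @param attribute Attribute name to group by.
#' @param split Evaluation split (default `"test"`); `NULL` uses all rows.
#' @param environment Optional environment filter.
#' @param thresholdPolicy `"f1"` (default) or a fixed numeric threshold.
#' @param nBins ECE bin count.
#' @return A data frame, one row per group, with the chosen threshold in
#'   `attr(x, "threshold")`.
#' @export
groupMetrics <- function(pred, attribute, split = "test", environment = NULL,
                         thresholdPolicy = "f1", nBins = 10L) {
  s <- predScores(pred, split = split, environment = environment)
  y <- predLabels(pred, split = split, environment = environment)
  g <- groupLabels(pred, attribute, split = split, environment = environment)
  if (!length(s)) validationError("no samples in the requested subset")
  thr <- resolveThreshold(s, y, thresholdPolicy)
  groups <- sort(unique(g))
  rows <- lapply(groups, function(gr) {
    idx <- g == gr
    cr <- confusionRates(s[idx], y[idx], thr)
    data.frame(group = gr, n = sum(idx), n_pos = sum(y[idx] == 1),
               tpr = cr$tpr, tnr = cr$tnr, fpr = cr$fpr, fnr = cr$fnr,
               auroc = aurocScore(s[idx], y[idx]),
               ece = if (sum(idx)) eceScore(s[idx], y[idx], nBins) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

gapMetricName <- function(polarity, overdiagnosis = FALSE) {
  # Underdiagnosis: falsely clearing ill patients. For a healthy-indicator
  # task that is a false positive; for a disease task a false negative. The
  # overdiagnosis flag swaps to the complementary rate.
  if (polarity == "healthy_indicator") {
    if (overdiagnosis) "fnr" else "fpr"
  } else {
    if (overdiagnosis) "fpr" else "fnr"
  }
}

#' Signed fairness gap between two designated groups
#'
#' Reports the signed difference `rate(group1) - rate(group2)` of the
#' class-conditional error rate picked by the task polarity: the FPR for a
#' healthy-indicator task and the FNR for a disease-indicator task
#' (underdiagnosis); `overdiagnosis = TRUE` swaps to the complementary rate.
#' The threshold is shared across groups (chosen on the ungrouped subset).
#'
#' @inheritParams groupMetrics
#' @param groupPair Character vector `c(group1, group2)`.
#' @param overdiagnosis Report the overdiagnosis mirror instead.
#' @param threshold Optional fixed threshold overriding `thresholdPolicy`.
#' @return A list of class `fairshift_gap` with elements `attribute`,
#'   `group1`, `group2`, `metric`, `rate1`, `rate2`, `signedGap`, `absGap`,
#'   `threshold`. Undefined rates yield an `NA` gap (with a message), not an
#'   error.
#' @export
fairnessGap <- function(pred, attribute, groupPair, split = "test",
                        environment = NULL, overdiagnosis = FALSE,
                        thresholdPolicy = "f1", threshold = NULL) {
  stopifnot(length(groupPair) == 2L)
  s <- predScores(pred, split = split, environment = environment)
  y <- predLabels(pred, split = split, environment = environment)
  g <- groupLabels(pred, attribute, split = split, environment = environment)
  thr <- if (!is.null(threshold)) threshold else resolveThreshold(s, y, thresholdPolicy)
  metric <- gapMetricName(taskPolarity(pred), overdiagnosis)
  rateOf <- function(gr) {
    idx <- g == gr
    if (!any(idx)) return(undefinedRate())
    confusionRates(s[idx], y[idx], thr)[[metric]]
  }
  r1 <- rateOf(groupPair[1L])
  r2 <- rateOf(groupPair[2L])
  gap <- r1 - r2
  if (is.na(gap)) message("fairnessGap: undefined rate in at least one group")
  structure(list(attribute = attribute, group1 = groupPair[1L],
                 group2 = groupPair[2L], metric = metric,
                 rate1 = r1, rate2 = r2,
                 signedGap = gap, absGap = abs(gap), threshold = thr),
            class = "fairshift_gap")
}

#' @export
print.fairshift_gap <- function(x, ...) {
  cat(sprintf("Fairness gap [%s] %s: %s - %s = %+0.4f (|gap| %0.4f, threshold %0.4f)\n",
              toupper(x$metric), x$attribute, x$group1, x$group2,
              x$signedGap, x$absGap, x$threshold))
  if (!is.null(x$ciLow)) {
    cat(sprintf("  bootstrap 95%% CI [%0.4f, %0.4f]%s\n", x$ciLow, x$ciHigh,
                if (isTRUE(x$significant)) " *" else ""))
  }
  invisible(x)
}

#' Bootstrap confidence interval for the fairness gap
#'
#' Percentile CI of the signed gap over `nBoot` nonparametric resamples of
#' the evaluation rows (resampling unit = sample row), at a threshold fixed
#' from the original data. Degenerate resamples in which either group loses
#' its conditioning class are redrawn (the redraw count is recorded).
#'
#' @inheritParams fairnessGap
#' @param nBoot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return A `fairshift_gap` with `ciLow`, `ciHigh`, `significant` (CI
#'   excludes 0), `nBoot`, `redraws` added.
#' @export
gapCI <- function(pred, attribute, groupPair, split = "test",
                  environment = NULL, overdiagnosis = FALSE,
                  thresholdPolicy = "f1", nBoot = 1000L, seed = 0L,
                  level = 0.95) {
  stopifnot(nBoot >= 1L)
  base <- fairnessGap(pred, attribute, groupPair, split = split,
                      environment = environment, overdiagnosis = overdiagnosis,
                      thresholdPolicy = thresholdPolicy)
  s <- predScores(pred, split = split, environment = environment)
  y <- predLabels(pred, split = split, environment = environment)
  g <- groupLabels(pred, attribute, split = split, environment = environment)
  thr <- base$threshold
  metric <- base$metric
  # class conditioned on: FPR needs negatives, FNR positives
  condClass <- if (metric == "fpr") 0 else 1
  err <- if (metric == "fpr") as.numeric(s >= thr) else as.numeric(s < thr)
  n <- length(s)
  in1 <- g == groupPair[1L]
  in2 <- g == groupPair[2L]
  inClass <- y == condClass
  set.seed(seed)
  gaps <- numeric(nBoot)
  redraws <- 0L
  for (b in seq_len(nBoot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      d1 <- in1[idx] & inClass[idx]
      d2 <- in2[idx] & inClass[idx]
      if (any(d1) && any(d2)) break
      redraws <- redraws + 1L
      if (redraws > 100L * nBoot) {
        validationError("gapCI: cannot draw non-degenerate resamples")
      }
    }
    gaps[b] <- mean(err[idx][d1]) - mean(err[idx][d2])
  }
  qs <- unname(quantile(gaps, c((1 - level) / 2, 1 - (1 - level) / 2), type = 7))
  base$ciLow <- qs[1L]
  base$ciHigh <- qs[2L]
  base$significant <- !is.na(qs[1L]) && (qs[1L] > 0 || qs[2L] < 0)
  base$nBoot <- nBoot
  base$redraws <- redraws
  base
}

#' Generic percentile bootstrap confidence interval
#'
#' @param x Numeric vector (the resampling units).
#' @param statistic Function mapping a numeric vector to a scalar.
#' @param nBoot Number of resamples.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return List with `estimate`, `ciLow`, `ciHigh`, `nBoot`.
#' @export
bootstrapCI <- function(x, statistic = mean, nBoot = 1000L, seed = 0L,
                        level = 0.95) {
  stopifnot(nBoot >= 1L, length(x) >= 1L)
  set.seed(seed)
  n <- length(x)
  idx <- matrix(sample.int(n, n * nBoot, replace = TRUE), nrow = n)
  stats <- if (identical(statistic, mean)) {
    colMeans(matrix(x[idx], nrow = n))
  } else {
    apply(idx, 2L, function(i) statistic(x[i]))
  }
  qs <- unname(quantile(stats, c((1 - level) / 2, 1 - (1 - level) / 2), type = 7))
  list(estimate = statistic(x), ciLow = qs[1L], ciHigh = qs[2L], nBoot = nBoot)
}

#' Rebalance an evaluation set across attribute combinations
#'
#' Subsamples (without replacement) so that every attribute-combination cell
#' has equal size and equal within-cell prevalence: for each class, every
#' cell is downsampled to the minimum per-cell count of that class.
#'
#' @param pred A [PredictionSet-class].
#' @param attributes Attribute names whose cross-product defines the cells.
#' @param split Split to rebalance (default `"test"`); other rows are
#'   dropped.
#' @param seed Integer seed.
#' @return A rebalanced [PredictionSet-class].
#' @export
rebalanceEvalSet <- function(pred, attributes, split = "test", seed = 0L) {
  ps <- if (is.null(split)) pred else filterSamples(pred, split = split)
  d <- ps@data
  if (!nrow(d)) validationError("no samples to rebalance")
  cell <- do.call(paste, c(d[attributes], sep = " / "))
  cells <- unique(cell)
  counts <- table(factor(cell, levels = cells), factor(d$label, levels = c(0, 1)))
  if (any(counts == 0)) {
    bad <- rownames(counts)[which(counts == 0, arr.ind = TRUE)[, 1L]]
    validationError(sprintf("empty (cell, class) for cell(s): %s",
                            paste(unique(bad), collapse = "; ")))
  }
  n0 <- min(counts[, "0"])
  n1 <- min(counts[, "1"])
  set.seed(seed)
  keep <- unlist(lapply(cells, function(cl) {
    i0 <- which(cell == cl & d$label == 0)
    i1 <- which(cell == cl & d$label == 1)
    c(i0[sample.int(length(i0), n0)], i1[sample.int(length(i1), n1)])
  }))
  keep <- sort(keep)
  d2 <- d[keep, , drop = FALSE]
  rownames(d2) <- NULL
  initialize(ps, data = d2)
}
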