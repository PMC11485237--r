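#' @include metrics.R
NULL

#' Per-model performance/fairness summary over one environment
#'
#' The grid-analysis workhorse: for every model, evaluates on one
#' environment and split the overall AUROC, worst-group AUROC, the signed
#' and absolute fairness gap for the designated group pair, overall ECE,
#' the ECE gap between the designated groups, and the worst-group
#' polarity error rate. The F1 threshold is chosen per model on the same
#' subset unless `threshold` fixes it.
#'
#' @param grid A [ModelGrid-class].
#' @param environment Environment id.
#' @param attribute Attribute name.
#' @param groupPair `c(group1, group2)` whose gap is reported.
#' @param split Split tag (default `"test"`).
#' @param thresholdPolicy `"f1"` or a numeric threshold.
#' @param nBins ECE bins.
#' @param overdiagnosis Report the overdiagnosis mirror gap.
#' @return Data frame, one row per model.
#' @export
gridSummary <- function(grid, environment, attribute, groupPair,
                        split = "test", thresholdPolicy = "f1", nBins = 10L,
                        overdiagnosis = FALSE) {
  rows <- lapply(gridEntries(grid), function(e) {
    ps <- e@predictions[[environment]]
    if (is.null(ps)) return(NULL)
    s <- predScores(ps, split = split)
    y <- predLabels(ps, split = split)
    gm <- groupMetrics(ps, attribute, split = split,
                       thresholdPolicy = thresholdPolicy, nBins = nBins)
    thr <- attr(gm, "threshold")
    gp <- fairnessGap(ps, attribute, groupPair, split = split,
                      overdiagnosis = overdiagnosis, threshold = thr)
    metric <- gp$metric
    e1 <- gm$ece[match(groupPair[1L], gm$group)]
    e2 <- gm$ece[match(groupPair[2L], gm$group)]
    data.frame(
      modelId = e@modelId, algorithm = e@algorithm,
      environment = environment,
      auroc = aurocScore(s, y),
      worstGroupAuroc = suppressWarnings(min(gm$auroc, na.rm = TRUE)),
      threshold = thr, metric = metric,
      signedGap = gp$signedGap, absGap = gp$absGap,
      ece = eceScore(s, y, nBins),
      eceGap = abs(e1 - e2),
      worstGroupRate = suppressWarnings(max(gm[[metric]], na.rm = TRUE)),
      n = length(s), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fairness-performance Pareto front
#'
#' Flags the models not strictly dominated in the joint objective (higher
#' performance, lower fairness gap). Dominance is weak with at least one
#' strict coordinate: point j dominates point i when
#' `performance_j >= performance_i` and `fairness_j <= fairness_i` with at
#' least one inequality strict. Exact ties stay on the front.
#'
#' @param points Data frame with columns `performance` and `fairness`
#'   (absolute gap), e.g. built from [gridSummary()].
#' @return The input with a logical `onFront` column.
#' @export
paretoFront <- function(points) {
  stopifnot(nrow(points) >= 1L,
            all(c("performance", "fairness") %in% names(points)))
  perf <- points$performance
  fair <- points$fairness
  stopifnot(all(is.finite(perf)), all(is.finite(fair)))
  n <- length(perf)
  on <- logical(n)
  ord <- order(-perf, fair)
  bestFairHigher <- Inf   # min fairness among strictly higher-performance points
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && perf[ord[j + 1L]] == perf[ord[i]]) j <- j + 1L
    groupIdx <- ord[i:j]
    gmin <- min(fair[groupIdx])
    if (gmin < bestFairHigher) {
      on[groupIdx[fair[groupIdx] == gmin]] <- TRUE
    }
    bestFairHigher <- min(bestFairHigher, gmin)
    i <- j + 1L
  }
  points$onFront <- on
  points
}

#' Best achievable fairness under a performance constraint
#'
#' Among points with `performance >= minPerformance`, returns the one with
#' the smallest fairness gap; ties break toward higher performance, then
#' lexically smallest `modelId`.
#'
#' @inheritParams paretoFront
#' @param minPerformance The performance floor.
#' @return The selected row of `points`.
#' @export
constrainedBestFairness <- function(points, minPerformance) {
  feas <- points[points$performance >= minPerformance, , drop = FALSE]
  if (!nrow(feas)) {
    validationError(sprintf(
      "no point meets performance >= %g (max available: %g)",
      minPerformance, max(points$performance)))
  }
  o <- order(feas$fairness, -feas$performance, as.character(feas$modelId))
  feas[o[1L], , drop = FALSE]
}

#' Pearson correlation with t-test p-value and Fisher-z CI
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with nonzero
#'   variance.
#' @param level Confidence level (default 0.95).
#' @return List with `r`, `p.value` (two-sided t-test on n-2 df), `ciLow`,
#'   `ciHigh` (Fisher z), `n`.
#' @export
pearsonWithCI <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) validationError("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) validationError("zero variance input")
  ct <- cor.test(x, y, method = "pearson", conf.level = level)
  ci <- if (!is.null(ct$conf.int)) ct$conf.int else c(NA_real_, NA_real_)
  list(r = unname(ct$estimate), p.value = ct$p.value,
       ciLow = ci[1L], ciHigh = ci[2L], n = n)
}

#' Correlation between attribute encoding and fairness gap across a grid
#'
#' Merges a per-model probe table (from [encodeGrid()]) with a per-model
#' fairness summary (from [gridSummary()]), drops models whose overall
#' validation AUROC falls below `performanceFloor` (default 0.7), and
#' correlates the attribute-probe AUROC with the absolute fairness gap.
#'
#' @param encodeTable Data frame with `modelId` and `probeAuroc`.
#' @param gapTable Data frame with `modelId` and `absGap`.
#' @param performanceTable Data frame with `modelId` and `auroc` used for
#'   the floor (typically the validation-split summary); `NULL` to skip
#'   filtering.
#' @param performanceFloor Overall AUROC floor (default 0.7).
#' @return [pearsonWithCI()] output plus `nExcluded`.
#' @export
encodingFairnessCorrelation <- function(encodeTable, gapTable,
                                        performanceTable = NULL,
                                        performanceFloor = 0.7) {
  m <- merge(encodeTable[c("modelId", "probeAuroc")],
             gapTable[c("modelId", "absGap")], by = "modelId")
  nAll <- nrow(m)
  if (!is.null(performanceTable)) {
    m <- merge(m, performanceTable[c("modelId", "auroc")], by = "modelId")
    m <- m[m$auroc >= performanceFloor, , drop = FALSE]
  }
  if (nrow(m) < 3L) {
    validationError("fewer than 3 models above the performance floor")
  }
  out <- pearsonWithCI(m$probeAuroc, m$absGap)
  out$nExcluded <- nAll - nrow(m)
  out
}

#' ID-to-OOD transfer correlation of performance or fairness
#'
#' Correlates, across models evaluated in both environments, the ID value
#' of a quantity with its OOD value. `"performance"` uses overall AUROC;
#' `"fairness"` uses the signed gap by default (a sign flip under shift is
#' precisely the non-transfer phenomenon of interest) or the absolute gap
#' via `useAbsGap`.
#'
#' @param grid A [ModelGrid-class].
#' @param idEnv,oodEnv Environment ids.
#' @param quantity `"performance"` or `"fairness"`.
#' @param attribute,groupPair,split Passed to [gridSummary()].
#' @param useAbsGap Correlate absolute rather than signed gaps.
#' @return [pearsonWithCI()] output.
#' @export
transferCorrelation <- function(grid, idEnv, oodEnv,
                                quantity = c("performance", "fairness"),
                                attribute, groupPair, split = "test",
                                useAbsGap = FALSE) {
  quantity <- match.arg(quantity)
  a <- gridSummary(grid, idEnv, attribute, groupPair, split = split)
  b <- gridSummary(grid, oodEnv, attribute, groupPair, split = split)
  m <- merge(a, b, by = "modelId", suffixes = c(".id", ".ood"))
  col <- if (quantity == "performance") "auroc" else if (useAbsGap) "absGap" else "signedGap"
  pearsonWithCI(m[[paste0(col, ".id")]], m[[paste0(col, ".ood")]])
}

#' Pareto-front membership in ID and OOD environments
#'
#' Computes the fairness-performance Pareto front separately in the two
#' environments and tabulates, per model, whether it lies on each front —
#' exposing models that are locally optimal in-distribution but lose
#' optimality after shift.
#'
#' @inheritParams transferCorrelation
#' @param useWorstGroup Use worst-group instead of overall AUROC as the
#'   performance axis.
#' @return Data frame with `modelId`, `onFrontID`, `onFrontOOD` and the
#'   underlying coordinates.
#' @export
frontTransfer <- function(grid, idEnv, oodEnv, attribute, groupPair,
                          split = "test", useWorstGroup = FALSE) {
  mk <- function(env) {
    gs <- gridSummary(grid, env, attribute, groupPair, split = split)
    data.frame(modelId = gs$modelId,
               performance = if (useWorstGroup) gs$worstGroupAuroc else gs$auroc,
               fairness = gs$absGap, stringsAsFactors = FALSE)
  }
  idPts <- paretoFront(mk(idEnv))
  oodPts <- paretoFront(mk(oodEnv))
  m <- merge(idPts, oodPts, by = "modelId", suffixes = c(".id", ".ood"))
  data.frame(modelId = m$modelId,
             performanceID = m$performance.id, fairnessID = m$fairness.id,
             onFrontID = m$onFront.id,
             performanceOOD = m$performance.ood, fairnessOOD = m$fairness.ood,
             onFrontOOD = m$onFront.ood, stringsAsFactors = FALSE)
}
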