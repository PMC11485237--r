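#' @include metrics.R
NULL

#' Per-group class-conditional error rate
#'
#' The mean of the per-sample loss over a group's conditioning class: for
#' FPR, the positive-prediction indicator averaged over true negatives in
#' the group; for FNR, the negative-prediction indicator over true
#' positives. These are exactly the sample-decomposable metrics the gap
#' decomposition operates on.
#'
#' @param pred A [PredictionSet-class].
#' @param attribute Attribute name.
#' @param group Group label.
#' @param metric `"fpr"` or `"fnr"`.
#' @param threshold Decision threshold (score >= threshold is positive).
#' @param split Split tag (default `"test"`).
#' @return The rate, or `NA` if the conditioning class is empty in the
#'   group.
#' @export
perGroupRate <- function(pred, attribute, group, metric = c("fpr", "fnr"),
                         threshold, split = "test") {
  metric <- match.arg(metric)
  s <- predScores(pred, split = split)
  y <- predLabels(pred, split = split)
  g <- groupLabels(pred, attribute, split = split)
  condClass <- if (metric == "fpr") 0 else 1
  idx <- g == group & y == condClass
  if (!any(idx)) return(undefinedRate())
  if (metric == "fpr") mean(s[idx] >= threshold) else mean(s[idx] < threshold)
}

#' Decompose the OOD fairness gap
#'
#' Writes the fairness gap of a model deployed in a target environment as
#' an exact identity in per-group error rates:
#' \deqn{L(g_1, D_{tar}) - L(g_2, D_{tar}) =
#'   [L(g_1, D_{src}) - L(g_2, D_{src})] +
#'   [L(g_2, D_{src}) - L(g_2, D_{tar})] -
#'   [L(g_1, D_{src}) - L(g_1, D_{tar})]}
#' i.e. OOD gap = ID gap + shift impact on group 2 - shift impact on group
#' 1, for any metric that is a mean of per-sample losses (FPR, FNR). The
#' identity holds algebraically; the `residual` field is reported as a
#' numerical check.
#'
#' By default the decision threshold is selected (or given) on the source
#' environment and reused on the target, so the decomposed object is
#' literally the same decision rule in both domains; `retuneOnTarget`
#' re-selects the threshold on the target for sensitivity analysis.
#'
#' @param entry A [ModelEntry-class] (or a named list of
#'   [PredictionSet-class] keyed by environment).
#' @param group1,group2 The two group labels (gap = group1 - group2).
#' @param srcEnv,tarEnv Source (ID) and target (OOD) environment ids.
#' @param attribute Attribute name.
#' @param metric `"fpr"`, `"fnr"`, or `NULL` to pick by task polarity
#'   (underdiagnosis rule).
#' @param split Evaluation split.
#' @param thresholdPolicy `"f1"` or a numeric threshold.
#' @param retuneOnTarget Re-select the threshold on the target environment.
#' @return A list of class `fairshift_decomposition` with the four per-cell
#'   rates, `termOODGap`, `termIDGap`, `termShiftG2`, `termShiftG1`,
#'   `residual` and bookkeeping fields.
#' @export
decomposeGap <- function(entry, group1, group2, srcEnv, tarEnv, attribute,
                         metric = NULL, split = "test",
                         thresholdPolicy = "f1", retuneOnTarget = FALSE) {
  preds <- if (is(entry, "ModelEntry")) entry@predictions else entry
  src <- preds[[srcEnv]]
  tar <- preds[[tarEnv]]
  if (is.null(src) || is.null(tar)) {
    validationError(sprintf("entry lacks environment '%s'",
                            if (is.null(src)) srcEnv else tarEnv))
  }
  if (is.null(metric)) metric <- gapMetricName(taskPolarity(src))
  thrSrc <- resolveThreshold(predScores(src, split = split),
                             predLabels(src, split = split), thresholdPolicy)
  thrTar <- if (retuneOnTarget) {
    resolveThreshold(predScores(tar, split = split),
                     predLabels(tar, split = split), thresholdPolicy)
  } else thrSrc

  L <- function(ps, group, thr) perGroupRate(ps, attribute, group, metric, thr, split)
  L1src <- L(src, group1, thrSrc)
  L2src <- L(src, group2, thrSrc)
  L1tar <- L(tar, group1, thrTar)
  L2tar <- L(tar, group2, thrTar)
  cells <- c(g1_src = L1src, g2_src = L2src, g1_tar = L1tar, g2_tar = L2tar)
  if (anyNA(cells)) {
    validationError(sprintf("undefined rate in cell(s): %s",
                            paste(names(cells)[is.na(cells)], collapse = ", ")))
  }
  termOOD <- L1tar - L2tar
  termID <- L1src - L2src
  shiftG2 <- L2src - L2tar
  shiftG1 <- L1src - L1tar
  structure(list(
    metric = metric, attribute = attribute, group1 = group1, group2 = group2,
    srcEnv = srcEnv, tarEnv = tarEnv,
    rateG1Src = L1src, rateG2Src = L2src, rateG1Tar = L1tar, rateG2Tar = L2tar,
    termOODGap = termOOD, termIDGap = termID,
    termShiftG2 = shiftG2, termShiftG1 = shiftG1,
    residual = abs(termOOD - (termID + shiftG2 - shiftG1)),
    thresholdSrc = thrSrc, thresholdTar = thrTar
  ), class = "fairshift_decomposition")
}

#' @export
print.fairshift_decomposition <- function(x, ...) {
  cat(sprintf("OOD %s gap decomposition (%s: %s - %s; %s -> %s)\n",
              toupper(x$metric), x$attribute, x$group1, x$group2,
              x$srcEnv, x$tarEnv))
  cat(sprintf("  OOD gap   %+0.4f\n", x$termOODGap))
  cat(sprintf("  = ID gap  %+0.4f\n", x$termIDGap))
  cat(sprintf("  + shift impact on %s  %+0.4f\n", x$group2, x$termShiftG2))
  cat(sprintf("  - shift impact on %s  %+0.4f\n", x$group1, x$termShiftG1))
  cat(sprintf("  residual %.2e\n", x$residual))
  invisible(x)
}

#' Decomposition table across a model grid
#'
#' Applies [decomposeGap()] to every (model, setting) combination and
#' summarizes which term dominates (largest absolute contribution among ID
#' gap and the two shift impacts). Settings referencing environments a
#' model was not evaluated in are skipped with a warning.
#'
#' @param grid A [ModelGrid-class].
#' @param settings Data frame with columns `tarEnv`, `attribute`, `group1`,
#'   `group2` (and optionally `srcEnv`, defaulting to the grid's ID
#'   environment).
#' @param split,thresholdPolicy,retuneOnTarget Passed to [decomposeGap()].
#' @return Data frame with one row per (model, setting).
#' @export
decompositionTable <- function(grid, settings, split = "test",
                               thresholdPolicy = "f1", retuneOnTarget = FALSE) {
  if (is.null(settings$srcEnv)) settings$srcEnv <- idEnvironment(grid)
  rows <- list()
  k <- 0L
  nSkipped <- 0L
  for (e in gridEntries(grid)) {
    for (i in seq_len(nrow(settings))) {
      st <- settings[i, ]
      if (!all(c(st$srcEnv, st$tarEnv) %in% names(e@predictions))) {
        nSkipped <- nSkipped + 1L
        next
      }
      d <- decomposeGap(e, st$group1, st$group2, st$srcEnv, st$tarEnv,
                        st$attribute, split = split,
                        thresholdPolicy = thresholdPolicy,
                        retuneOnTarget = retuneOnTarget)
      terms <- c(idGap = abs(d$termIDGap), shiftG2 = abs(d$termShiftG2),
                 shiftG1 = abs(d$termShiftG1))
      rows[[k <- k + 1L]] <- data.frame(
        modelId = e@modelId, algorithm = e@algorithm,
        srcEnv = st$srcEnv, tarEnv = st$tarEnv, attribute = st$attribute,
        group1 = st$group1, group2 = st$group2, metric = d$metric,
        oodGap = d$termOODGap, idGap = d$termIDGap,
        shiftG2 = d$termShiftG2, shiftG1 = d$termShiftG1,
        residual = d$residual,
        dominantTerm = names(terms)[which.max(terms)],
        stringsAsFactors = FALSE)
    }
  }
  if (nSkipped) warning(sprintf("%d unevaluated (model, setting) pairs skipped", nSkipped))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
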