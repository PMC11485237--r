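#' @include AllGenerics.R
NULL

defaultLambdaGrid <- function() 10^seq(-5, 1, length.out = 7)

macroAurocFromProbs <- function(P, g, classes) {
  per <- vapply(classes, function(cl) aurocScore(P[, cl], as.numeric(g == cl)),
                numeric(1))
  list(perClass = per, macro = mean(per, na.rm = TRUE))
}

#' Fit a demographic-attribute linear probe on frozen embeddings
#'
#' Trains an L2-regularized multinomial logistic regression ("linear probe")
#' on frozen embedding vectors to predict the demographic group, for each
#' regularization strength in `lambdaGrid`, and keeps the strength with the
#' best macro-averaged one-vs-rest AUROC on the validation embeddings. The
#' resulting probe AUROC is the package's measure of how much demographic
#' information a model's representation encodes.
#'
#' Features are standardized with the training-split mean and standard
#' deviation before fitting so that one regularization scale is comparable
#' across embedding spaces. The default grid spans strengths from 1e-5 to 10
#' on 7 log-spaced points.
#'
#' @param embTrain,embVal Training / validation [EmbeddingSet-class].
#' @param attribute Attribute to predict.
#' @param lambdaGrid Vector of L2 strengths.
#' @param trainSplit,valSplit Split tags to select rows from the two sets.
#' @param maxit Solver iteration cap; exceeding it sets `converged = FALSE`
#'   (a flag, not a failure).
#' @return An object of class `fairshiftProbe`: the fitted coefficients, the
#'   selected strength `lambda`, per-strength validation macro AUROCs, the
#'   standardization parameters and the class levels.
#' @seealso [probeAuroc()], [encodeGrid()]
#' @export
fitProbe <- function(embTrain, embVal, attribute,
                     lambdaGrid = defaultLambdaGrid(),
                     trainSplit = "train", valSplit = "val", maxit = 1e5) {
  xtr <- embMatrix(embTrain, split = trainSplit)
  gtr <- groupLabels(embTrain, attribute, split = trainSplit)
  xval <- embMatrix(embVal, split = valSplit)
  gval <- groupLabels(embVal, attribute, split = valSplit)
  if (!nrow(xval)) validationError("validation set is empty")
  classes <- sort(unique(gtr))
  if (length(classes) < 2L) {
    validationError("probe requires at least two attribute classes in training data")
  }
  center <- colMeans(xtr)
  scale <- apply(xtr, 2L, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  ztr <- scale(xtr, center = center, scale = scale)
  zval <- scale(xval, center = center, scale = scale)

  lam <- sort(unique(lambdaGrid), decreasing = TRUE)
  fit <- glmnet::glmnet(ztr, factor(gtr, levels = classes),
                        family = "multinomial", alpha = 0, lambda = lam,
                        standardize = FALSE, maxit = maxit)
  P <- predict(fit, newx = zval, type = "response")  # nval x nclass x nlambda
  valAuroc <- vapply(seq_along(lam), function(l) {
    macroAurocFromProbs(P[, , l, drop = FALSE][, , 1L], gval, classes)$macro
  }, numeric(1))
  # ties resolve to the first (largest) strength: prefer the more
  # regularized probe at equal validation AUROC
  bestIdx <- which.max(valAuroc)
  structure(list(
    fit = fit, attribute = attribute, classes = classes,
    lambdaGrid = lam, lambda = lam[bestIdx], lambdaIndex = bestIdx,
    valMacroAuroc = valAuroc, center = center, scale = scale,
    converged = fit$npasses < maxit
  ), class = "fairshiftProbe")
}

#' @export
print.fairshiftProbe <- function(x, ...) {
  cat(sprintf("Linear probe for '%s' (%d classes)\n", x$attribute,
              length(x$classes)))
  cat(sprintf("  selected L2 strength: %g (val macro AUROC %0.4f)\n",
              x$lambda, x$valMacroAuroc[x$lambdaIndex]))
  if (!x$converged) cat("  warning: solver iteration cap reached\n")
  invisible(x)
}

probeProbs <- function(probe, emb, split = "test") {
  x <- embMatrix(emb, split = split)
  z <- scale(x, center = probe$center, scale = probe$scale)
  P <- predict(probe$fit, newx = z, type = "response",
               s = probe$lambdaGrid[probe$lambdaIndex])[, , 1L]
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L, dimnames = list(NULL, probe$classes))
  P
}

#' Evaluate a fitted probe on held-out embeddings
#'
#' Computes the one-vs-rest AUROC per class and their unweighted
#' (macro) mean, plus the argmax-class attribute prediction accuracy, on a
#' test split.
#'
#' @param probe A `fairshiftProbe` from [fitProbe()].
#' @param embTest Test [EmbeddingSet-class].
#' @param split Split tag (default `"test"`).
#' @return List with `macroAuroc`, `perClassAuroc`, `accuracy`, `n`.
#' @export
probeAuroc <- function(probe, embTest, split = "test") {
  g <- groupLabels(embTest, probe$attribute, split = split)
  unseen <- setdiff(unique(g), probe$classes)
  if (length(unseen)) {
    validationError(sprintf("test set contains unseen class(es): %s",
                            paste(unseen, collapse = ", ")))
  }
  P <- probeProbs(probe, embTest, split = split)
  ma <- macroAurocFromProbs(P, g, probe$classes)
  predClass <- probe$classes[max.col(P, ties.method = "first")]
  list(macroAuroc = ma$macro, perClassAuroc = ma$perClass,
       accuracy = mean(predClass == g), n = length(g))
}

#' Probe attribute encoding for every model in a grid
#'
#' Fits a linear probe per model (training and selecting on the model's own
#' embedding splits) and tabulates the test macro AUROC and accuracy — the
#' per-model attribute-encoding measures used by the encoding-fairness
#' correlation and the selection criteria. Models without embeddings in the
#' requested environment are skipped with a warning.
#'
#' @param grid A [ModelGrid-class].
#' @param attribute Attribute to probe.
#' @param environment Environment id (default: the grid's ID environment).
#' @param lambdaGrid L2 strengths (see [fitProbe()]).
#' @return Data frame with one row per probed model: `modelId`, `algorithm`,
#'   `lambda`, `valMacroAuroc`, `probeAuroc`, `probeAccuracy`, `converged`.
#' @export
encodeGrid <- function(grid, attribute, environment = idEnvironment(grid),
                       lambdaGrid = defaultLambdaGrid()) {
  rows <- list()
  skipped <- character()
  for (e in gridEntries(grid)) {
    emb <- e@embeddings[[environment]]
    if (is.null(emb)) {
      skipped <- c(skipped, e@modelId)
      next
    }
    pr <- fitProbe(emb, emb, attribute, lambdaGrid = lambdaGrid)
    te <- probeAuroc(pr, emb)
    rows[[e@modelId]] <- data.frame(
      modelId = e@modelId, algorithm = e@algorithm, lambda = pr$lambda,
      valMacroAuroc = pr$valMacroAuroc[pr$lambdaIndex],
      probeAuroc = te$macroAuroc, probeAccuracy = te$accuracy,
      converged = pr$converged, stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    warning(sprintf("model(s) without embeddings skipped: %s",
                    paste(skipped, collapse = ", ")))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
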