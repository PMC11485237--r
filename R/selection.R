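#' @include analysis.R
NULL

#' Registry of ID-computable model selection criteria
#'
#' Each criterion scores a model using in-distribution data only (the
#' deployment setting observes no OOD samples) and selects by minimizing or
#' maximizing that score. Three criteria target the demographic-shortcut
#' mechanism directly (minimum ID fairness gap, minimum attribute-probe
#' AUROC, minimum attribute-probe accuracy); the rest are standard
#' performance/calibration selections. The registry is configuration: any
#' subset, or additional criteria over columns of the score table, can be
#' supplied to [evaluateCriteria()].
#'
#' @return Data frame with `name`, `column` (score-table column) and
#'   `direction` (`"minimize"`/`"maximize"`).
#' @export
defaultCriteria <- function() {
  data.frame(
    name = c("Minimum Fairness Gap",
             "Minimum Attribute Prediction AUROC",
             "Minimum Attribute Prediction Accuracy",
             "Maximum Overall AUROC",
             "Maximum Worst-Group AUROC",
             "Minimum ECE Gap",
             "Minimum Overall ECE",
             "Minimum Worst-Group Error Rate"),
    column = c("absGap", "probeAuroc", "probeAccuracy", "auroc",
               "worstGroupAuroc", "eceGap", "ece", "worstGroupRate"),
    direction = c("minimize", "minimize", "minimize", "maximize",
                  "maximize", "minimize", "minimize", "minimize"),
    stringsAsFactors = FALSE)
}

#' Per-model ID score table for selection criteria
#'
#' Builds the table the criteria operate on: the ID validation-split
#' performance/fairness summary ([gridSummary()]) merged with the
#' attribute-probe table ([encodeGrid()]).
#'
#' @param grid A [ModelGrid-class].
#' @param attribute,groupPair Audit attribute and designated group pair.
#' @param probeTable Optional precomputed [encodeGrid()] output (reused
#'   across settings); computed on demand when `NULL` and embeddings exist.
#' @param split ID split scored by the criteria (default `"val"`).
#' @return Data frame, one row per model.
#' @export
criterionScores <- function(grid, attribute, groupPair, probeTable = NULL,
                            split = "val") {
  idTbl <- gridSummary(grid, idEnvironment(grid), attribute, groupPair,
                       split = split)
  if (is.null(probeTable)) {
    hasEmb <- any(vapply(gridEntries(grid),
                         function(e) idEnvironment(grid) %in% names(e@embeddings),
                         logical(1)))
    if (hasEmb) probeTable <- encodeGrid(grid, attribute)
  }
  if (!is.null(probeTable)) {
    idTbl <- merge(idTbl, probeTable[c("modelId", "probeAuroc", "probeAccuracy")],
                   by = "modelId", all.x = TRUE)
  }
  idTbl[order(idTbl$modelId), , drop = FALSE]
}

#' Filter a score table by the satisfactory-performance rule
#'
#' Keeps models whose ID validation AUROC is no more than 5 percent below
#' the best reference-algorithm model. The default reading is relative
#' (`auroc >= (1 - margin) * best`); `rule = "absolute"` subtracts the
#' margin instead.
#'
#' @param scoreTable Output of [criterionScores()].
#' @param referenceAlgorithm Algorithm tag anchoring the cutoff.
#' @param rule `"relative"` or `"absolute"`.
#' @param margin Cutoff margin (default 0.05).
#' @return The surviving rows, with the cutoff in `attr(x, "cutoff")`.
#' @export
performanceFilter <- function(scoreTable, referenceAlgorithm = "erm-like",
                              rule = c("relative", "absolute"), margin = 0.05) {
  rule <- match.arg(rule)
  ref <- scoreTable$auroc[scoreTable$algorithm == referenceAlgorithm]
  if (!length(ref)) {
    validationError(sprintf("no model with reference algorithm '%s'",
                            referenceAlgorithm))
  }
  best <- max(ref)
  cutoff <- if (rule == "relative") (1 - margin) * best else best - margin
  out <- scoreTable[scoreTable$auroc >= cutoff, , drop = FALSE]
  if (!nrow(out)) validationError("performance filter removed every model")
  attr(out, "cutoff") <- cutoff
  out
}

selectFromTable <- function(tbl, column, direction) {
  sc <- tbl[[column]]
  if (is.null(sc) || all(is.na(sc))) {
    validationError(sprintf("criterion input column '%s' unavailable", column))
  }
  keep <- !is.na(sc)
  tbl <- tbl[keep, , drop = FALSE]
  sc <- sc[keep]
  if (direction == "maximize") sc <- -sc
  o <- order(sc, -tbl$auroc, as.character(tbl$modelId))
  tbl$modelId[o[1L]]
}

#' Apply one selection criterion to a (filtered) score table
#'
#' Deterministic argmin/argmax of the criterion column; ties break toward
#' higher ID overall AUROC, then lexically smallest model id.
#'
#' @param scoreTable (Filtered) output of [criterionScores()].
#' @param criterion A criterion name from [defaultCriteria()], or a
#'   one-row data frame with `column` and `direction`.
#' @return The chosen `modelId`.
#' @export
applyCriterion <- function(scoreTable, criterion) {
  if (is.character(criterion)) {
    reg <- defaultCriteria()
    i <- match(criterion, reg$name)
    if (is.na(i)) validationError(sprintf("unknown criterion '%s'", criterion))
    criterion <- reg[i, ]
  }
  selectFromTable(scoreTable, criterion$column, criterion$direction)
}

#' Oracle model selection on OOD fairness
#'
#' The oracle observes target-environment samples and picks the model with
#' the smallest absolute OOD fairness gap (same tie rule as
#' [applyCriterion()]).
#'
#' @param oodTable Per-model OOD summary ([gridSummary()] on the target
#'   environment) restricted to the filtered subset.
#' @return The oracle's `modelId`.
#' @export
oracleSelect <- function(oodTable) {
  if (!nrow(oodTable)) validationError("no OOD evaluation available")
  selectFromTable(oodTable, "absGap", "minimize")
}

#' One-tailed rank-sum comparison of two regret samples
#'
#' Wilcoxon rank-sum (Mann-Whitney) p-value for the alternative that the
#' first sample is stochastically smaller. Uses exact enumeration when both
#' samples are tie-free and the combined size is at most 50, and the normal
#' approximation with tie correction otherwise.
#'
#' @param regretsA,regretsB Numeric vectors.
#' @return The one-tailed p-value.
#' @export
#' @examples
#' compareCriteria(c(1, 2, 3), c(4, 5, 6)) # exact 1/20
compareCriteria <- function(regretsA, regretsB) {
  stopifnot(length(regretsA) >= 1L, length(regretsB) >= 1L)
  hasTies <- anyDuplicated(c(regretsA, regretsB)) > 0L
  useExact <- !hasTies && (length(regretsA) + length(regretsB)) <= 50L
  wilcox.test(regretsA, regretsB, alternative = "less",
              exact = useExact, correct = FALSE)$p.value
}

settingLabel <- function(st) {
  paste(st$tarEnv, st$attribute, paste(st$group1, st$group2, sep = "|"), sep = " / ")
}

#' Evaluate model selection criteria against the OOD oracle
#'
#' For every setting (target environment x attribute x group pair):
#' applies the satisfactory-performance filter, lets each criterion choose
#' a model from ID data, evaluates the chosen model's absolute OOD fairness
#' gap, and measures the regret against the oracle (which picks the
#' smallest OOD gap within the same filtered subset). Aggregates mean
#' regret per criterion with a percentile bootstrap CI over settings
#' (resampling unit = setting) and all pairwise one-tailed rank-sum
#' p-values.
#'
#' @param grid A [ModelGrid-class] with embeddings (for the probe
#'   criteria).
#' @param settings Data frame with `tarEnv`, `attribute`, `group1`,
#'   `group2`.
#' @param criteria Criterion registry (default [defaultCriteria()]).
#' @param nBoot Bootstrap resamples over settings.
#' @param seed Integer seed.
#' @param referenceAlgorithm,filterRule,filterMargin Performance-filter
#'   parameters.
#' @return A list of class `fairshift_selection_report`: `perSetting` (one
#'   row per setting x criterion with chosen/oracle models, gaps, regret),
#'   `summary` (per-criterion mean regret and CI), `wilcoxon` (matrix of
#'   one-tailed p-values, entry \[a, b\] testing regret(a) < regret(b)).
#' @export
evaluateCriteria <- function(grid, settings, criteria = defaultCriteria(),
                             nBoot = 1000L, seed = 0L,
                             referenceAlgorithm = "erm-like",
                             filterRule = "relative", filterMargin = 0.05) {
  stopifnot(nrow(settings) >= 1L, nBoot >= 1L)
  probeCache <- list()
  rows <- list()
  k <- 0L
  skipped <- character()
  for (i in seq_len(nrow(settings))) {
    st <- settings[i, ]
    pair <- c(st$group1, st$group2)
    if (is.null(probeCache[[st$attribute]])) {
      probeCache[[st$attribute]] <- encodeGrid(grid, st$attribute)
    }
    scores <- criterionScores(grid, st$attribute, pair,
                              probeTable = probeCache[[st$attribute]])
    sub <- tryCatch(
      performanceFilter(scores, referenceAlgorithm, filterRule, filterMargin),
      fairshift_validation_error = function(e) NULL)
    if (is.null(sub)) {
      skipped <- c(skipped, settingLabel(st))
      next
    }
    ood <- gridSummary(grid, st$tarEnv, st$attribute, pair, split = "test")
    ood <- ood[ood$modelId %in% sub$modelId, , drop = FALSE]
    if (!nrow(ood)) {
      skipped <- c(skipped, settingLabel(st))
      next
    }
    oracleId <- oracleSelect(ood)
    oracleGap <- ood$absGap[ood$modelId == oracleId]
    for (j in seq_len(nrow(criteria))) {
      cr <- criteria[j, ]
      chosenId <- applyCriterion(sub, cr)
      chosenGap <- ood$absGap[ood$modelId == chosenId]
      rows[[k <- k + 1L]] <- data.frame(
        setting = settingLabel(st), tarEnv = st$tarEnv,
        attribute = st$attribute, criterion = cr$name,
        chosenModel = chosenId, chosenGap = chosenGap,
        oracleModel = oracleId, oracleGap = oracleGap,
        regret = chosenGap - oracleGap, stringsAsFactors = FALSE)
    }
  }
  if (length(skipped)) {
    warning(sprintf("setting(s) skipped (empty filtered subset): %s",
                    paste(skipped, collapse = "; ")))
  }
  perSetting <- do.call(rbind, rows)
  if (is.null(perSetting)) validationError("no evaluable settings")
  rownames(perSetting) <- NULL

  critNames <- unique(perSetting$criterion)
  regrets <- lapply(critNames, function(nm) perSetting$regret[perSetting$criterion == nm])
  names(regrets) <- critNames

  summary <- do.call(rbind, lapply(seq_along(critNames), function(j) {
    ci <- bootstrapCI(regrets[[j]], mean, nBoot = nBoot,
                      seed = deriveSeed(seed, j))
    data.frame(criterion = critNames[j], meanRegret = ci$estimate,
               ciLow = ci$ciLow, ciHigh = ci$ciHigh,
               nSettings = length(regrets[[j]]), stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL

  W <- matrix(NA_real_, length(critNames), length(critNames),
              dimnames = list(critNames, critNames))
  for (a in critNames) {
    for (b in critNames) {
      if (a != b) W[a, b] <- compareCriteria(regrets[[a]], regrets[[b]])
    }
  }
  structure(list(perSetting = perSetting, summary = summary, wilcoxon = W,
                 nBoot = nBoot, seed = seed, skippedSettings = skipped),
            class = "fairshift_selection_report")
}

#' @export
print.fairshift_selection_report <- function(x, ...) {
  cat("Model selection vs OOD oracle\n")
  s <- x$summary[order(x$summary$meanRegret), ]
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-40s mean regret %0.4f [%0.4f, %0.4f] over %d settings\n",
                s$criterion[i], s$meanRegret[i], s$ciLow[i], s$ciHigh[i],
                s$nSettings[i]))
  }
  invisible(x)
}

#' Per-algorithm OOD fairness view
#'
#' Within each algorithm family, applies the performance filter (cutoff
#' anchored on the reference algorithm across the whole grid) and selects
#' the model with the minimum ID fairness gap; its OOD gap is compared
#' against the global oracle of each setting. Algorithms with no surviving
#' model in a setting are skipped with a warning.
#'
#' @inheritParams evaluateCriteria
#' @return A `fairshift_selection_report` whose rows are keyed by algorithm
#'   instead of criterion.
#' @export
perAlgorithmView <- function(grid, settings, nBoot = 1000L, seed = 0L,
                             referenceAlgorithm = "erm-like",
                             filterRule = "relative", filterMargin = 0.05) {
  probeCache <- list()
  rows <- list()
  k <- 0L
  nSkipped <- 0L
  for (i in seq_len(nrow(settings))) {
    st <- settings[i, ]
    pair <- c(st$group1, st$group2)
    if (is.null(probeCache[[st$attribute]])) {
      probeCache[[st$attribute]] <- encodeGrid(grid, st$attribute)
    }
    scores <- criterionScores(grid, st$attribute, pair,
                              probeTable = probeCache[[st$attribute]])
    sub <- performanceFilter(scores, referenceAlgorithm, filterRule, filterMargin)
    ood <- gridSummary(grid, st$tarEnv, st$attribute, pair, split = "test")
    ood <- ood[ood$modelId %in% sub$modelId, , drop = FALSE]
    oracleId <- oracleSelect(ood)
    oracleGap <- ood$absGap[ood$modelId == oracleId]
    for (alg in sort(unique(scores$algorithm))) {
      salg <- sub[sub$algorithm == alg, , drop = FALSE]
      if (!nrow(salg)) {
        nSkipped <- nSkipped + 1L
        next
      }
      chosenId <- selectFromTable(salg, "absGap", "minimize")
      chosenGap <- ood$absGap[ood$modelId == chosenId]
      rows[[k <- k + 1L]] <- data.frame(
        setting = settingLabel(st), tarEnv = st$tarEnv,
        attribute = st$attribute, criterion = alg,
        chosenModel = chosenId, chosenGap = chosenGap,
        oracleModel = oracleId, oracleGap = oracleGap,
        regret = chosenGap - oracleGap, stringsAsFactors = FALSE)
    }
  }
  if (nSkipped) warning(sprintf("%d (algorithm, setting) pairs had no surviving model", nSkipped))
  perSetting <- do.call(rbind, rows)
  rownames(perSetting) <- NULL
  algs <- unique(perSetting$criterion)
  regrets <- lapply(algs, function(a) perSetting$regret[perSetting$criterion == a])
  names(regrets) <- algs
  summary <- do.call(rbind, lapply(seq_along(algs), function(j) {
    ci <- bootstrapCI(regrets[[j]], mean, nBoot = nBoot, seed = deriveSeed(seed, j))
    data.frame(criterion = algs[j], meanRegret = ci$estimate,
               ciLow = ci$ciLow, ciHigh = ci$ciHigh,
               nSettings = length(regrets[[j]]), stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  W <- matrix(NA_real_, length(algs), length(algs), dimnames = list(algs, algs))
  for (a in algs) for (b in algs) {
    if (a != b) W[a, b] <- compareCriteria(regrets[[a]], regrets[[b]])
  }
  structure(list(perSetting = perSetting, summary = summary, wilcoxon = W,
                 nBoot = nBoot, seed = seed, skippedSettings = character()),
            class = "fairshift_selection_report")
}
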