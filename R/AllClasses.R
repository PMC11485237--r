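#' @include fairshift-package.R
NULL

REQUIRED_PRED_COLUMNS <- c("sample_id", "score", "label", "split", "environment", "task")
VALID_SPLITS <- c("train", "val", "test")
VALID_POLARITIES <- c("healthy_indicator", "disease_indicator")

# ---------------------------------------------------------------------------
# PredictionSet
# ---------------------------------------------------------------------------

#' PredictionSet: per-sample scores, labels and demographic attributes
#'
#' A `PredictionSet` holds the evaluation table for one model on one task:
#' per-sample predicted probability, binary outcome, demographic attribute
#' labels, split tag (`train`/`val`/`test`) and environment (dataset/domain)
#' id. It is the unit container consumed by every fairness and shift
#' operation.
#'
#' @slot data A `data.frame` with columns `sample_id`, `score`, `label`,
#'   `split`, `environment`, `task`, plus one column per demographic
#'   attribute.
#' @slot attrNames Character vector naming the attribute columns.
#' @slot task Task name (single string).
#' @slot taskPolarity Either `"healthy_indicator"` (the positive class means
#'   "no disease", so underdiagnosis is a false positive) or
#'   `"disease_indicator"` (underdiagnosis is a false negative).
#'
#' @seealso [predictionSet()], [groupMetrics()], [fairnessGap()]
#' @exportClass PredictionSet
setClass("PredictionSet",
  representation(
    data = "data.frame",
    attrNames = "character",
    task = "character",
    taskPolarity = "character"
  )
)

setValidity("PredictionSet", function(object) {
  d <- object@data
  missingCols <- setdiff(c(REQUIRED_PRED_COLUMNS, object@attrNames), names(d))
  if (length(missingCols)) {
    return(sprintf("missing columns: %s", paste(missingCols, collapse = ", ")))
  }
  if (length(object@taskPolarity) != 1L ||
      !object@taskPolarity %in% VALID_POLARITIES) {
    return(sprintf("taskPolarity must be one of %s",
                   paste(VALID_POLARITIES, collapse = ", ")))
  }
  if (nrow(d)) {
    if (anyNA(d$score) || any(d$score < 0 | d$score > 1)) {
      return("scores must lie in [0, 1]")
    }
    if (!all(d$label %in% c(0, 1))) return("labels must be 0 or 1")
    if (!all(d$split %in% VALID_SPLITS)) {
      return(sprintf("split must be one of %s", paste(VALID_SPLITS, collapse = ", ")))
    }
    for (a in object@attrNames) {
      if (anyNA(d[[a]])) return(sprintf("attribute '%s' contains missing values", a))
    }
    key <- paste(d$environment, d$split, d$sample_id, sep = "\r")
    if (anyDuplicated(key)) {
      return("sample_id values must be unique within (environment, split)")
    }
  }
  TRUE
})

#' Construct a PredictionSet
#'
#' @param data Data frame with the required columns (see
#'   [PredictionSet-class]) and one column per attribute.
#' @param attrNames Names of the demographic attribute columns. Defaults to
#'   all columns not among the required ones.
#' @param task Task name; defaults to the unique value of `data$task`.
#' @param taskPolarity `"healthy_indicator"` or `"disease_indicator"`.
#' @return A validated [PredictionSet-class] object.
#' @export
#' @examples
#' d <- data.frame(
#'   sample_id = paste0("s", 1:4), score = c(0.1, 0.6, 0.8, 0.3),
#'   label = c(0, 1, 1, 0), split = "test", environment = "site_a",
#'   task = "disease", sex = c("female", "male", "female", "male")
#' )
#' predictionSet(d)
predictionSet <- function(data, attrNames = NULL,
                          task = NULL,
                          taskPolarity = "disease_indicator") {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (is.null(attrNames)) attrNames <- setdiff(names(data), REQUIRED_PRED_COLUMNS)
  if (is.null(task)) {
    task <- if (nrow(data)) as.character(data$task[1L]) else "task"
  }
  data$sample_id <- as.character(data$sample_id)
  new("PredictionSet", data = data, attrNames = attrNames,
      task = task, taskPolarity = taskPolarity)
}

# ---------------------------------------------------------------------------
# EmbeddingSet
# ---------------------------------------------------------------------------

#' EmbeddingSet: per-sample representation vectors
#'
#' Holds the frozen model representations f(X) aligned to a
#' [PredictionSet-class]: an n x d numeric matrix with one row per sample,
#' plus the sample annotations (attributes, split, environment) needed to
#' probe or test the representations by demographic group.
#'
#' @slot embeddings Numeric n x d matrix, all entries finite; rownames are
#'   sample ids.
#' @slot sampleData Data frame with `sample_id`, `split`, `environment` and
#'   attribute columns, row-aligned to `embeddings`.
#' @slot attrNames Names of the attribute columns in `sampleData`.
#' @seealso [embeddingSet()], [fitProbe()], [mmdPermutationTest()]
#' @exportClass EmbeddingSet
setClass("EmbeddingSet",
  representation(
    embeddings = "matrix",
    sampleData = "data.frame",
    attrNames = "character"
  )
)

setValidity("EmbeddingSet", function(object) {
  m <- object@embeddings
  sd <- object@sampleData
  if (!is.numeric(m)) return("embeddings must be numeric")
  if (nrow(m) != nrow(sd)) return("embeddings and sampleData must have equal row counts")
  if (nrow(m) && !all(is.finite(m))) return("embeddings must be finite (no NA/NaN/Inf)")
  need <- c("sample_id", "split", "environment", object@attrNames)
  missingCols <- setdiff(need, names(sd))
  if (length(missingCols)) {
    return(sprintf("sampleData missing columns: %s", paste(missingCols, collapse = ", ")))
  }
  if (nrow(sd)) {
    key <- paste(sd$environment, sd$split, sd$sample_id, sep = "\r")
    if (anyDuplicated(key)) return("one embedding vector per sample_id required")
  }
  TRUE
})

#' Construct an EmbeddingSet
#'
#' @param embeddings Numeric matrix (samples x dimensions).
#' @param sampleData Data frame with `sample_id`, `split`, `environment` and
#'   attribute columns, one row per embedding row.
#' @param attrNames Attribute column names; defaults to the non-reserved
#'   columns of `sampleData`.
#' @return A validated [EmbeddingSet-class].
#' @export
embeddingSet <- function(embeddings, sampleData, attrNames = NULL) {
  sampleData <- as.data.frame(sampleData, stringsAsFactors = FALSE)
  sampleData$sample_id <- as.character(sampleData$sample_id)
  if (is.null(attrNames)) {
    attrNames <- setdiff(names(sampleData), c("sample_id", "split", "environment"))
  }
  embeddings <- as.matrix(embeddings)
  rownames(embeddings) <- sampleData$sample_id
  new("EmbeddingSet", embeddings = embeddings, sampleData = sampleData,
      attrNames = attrNames)
}

# ---------------------------------------------------------------------------
# ModelEntry / ModelGrid
# ---------------------------------------------------------------------------

#' ModelEntry: one model's evaluations across environments
#'
#' @slot modelId Unique model identifier.
#' @slot algorithm Training-algorithm tag (e.g. `"erm-like"`).
#' @slot hparamTag Hyperparameter tag.
#' @slot seed Training seed tag.
#' @slot predictions Named list mapping environment id to
#'   [PredictionSet-class].
#' @slot embeddings Named list mapping environment id to
#'   [EmbeddingSet-class]; may be empty.
#' @seealso [modelEntry()], [assembleGrid()]
#' @exportClass ModelEntry
setClass("ModelEntry",
  representation(
    modelId = "character",
    algorithm = "character",
    hparamTag = "character",
    seed = "integer",
    predictions = "list",
    embeddings = "list"
  )
)

setValidity("ModelEntry", function(object) {
  if (length(object@modelId) != 1L || !nzchar(object@modelId)) {
    return("modelId must be a non-empty string")
  }
  if (!length(object@predictions)) return("entry must carry at least one PredictionSet")
  if (is.null(names(object@predictions)) || any(!nzchar(names(object@predictions)))) {
    return("predictions must be a named list keyed by environment")
  }
  for (p in object@predictions) {
    if (!is(p, "PredictionSet")) return("predictions must contain PredictionSet objects")
  }
  if (length(object@embeddings)) {
    if (is.null(names(object@embeddings))) return("embeddings must be named by environment")
    for (e in object@embeddings) {
      if (!is(e, "EmbeddingSet")) return("embeddings must contain EmbeddingSet objects")
    }
  }
  TRUE
})

#' Construct a ModelEntry
#'
#' @param modelId Unique model id.
#' @param predictions Named list (environment -> [PredictionSet-class]).
#' @param embeddings Optional named list (environment ->
#'   [EmbeddingSet-class]).
#' @param algorithm,hparamTag,seed Model provenance tags.
#' @return A [ModelEntry-class].
#' @export
modelEntry <- function(modelId, predictions, embeddings = list(),
                       algorithm = "unknown", hparamTag = "", seed = 0L) {
  new("ModelEntry", modelId = as.character(modelId), algorithm = algorithm,
      hparamTag = hparamTag, seed = as.integer(seed),
      predictions = predictions, embeddings = embeddings)
}

#' ModelGrid: a collection of models under audit
#'
#' The grid of models (algorithm x hyperparameters x seed) whose outputs are
#' analysed jointly: Pareto fronts, encoding-fairness correlations, transfer
#' correlations and model selection all operate on a `ModelGrid`.
#'
#' @slot entries Named list of [ModelEntry-class], keyed by model id.
#' @slot idEnvironment The designated in-distribution environment id; every
#'   entry must cover it.
#' @seealso [assembleGrid()], [gridSummary()]
#' @exportClass ModelGrid
setClass("ModelGrid",
  representation(entries = "list", idEnvironment = "character")
)

setValidity("ModelGrid", function(object) {
  if (!length(object@entries)) return("grid must contain at least one entry")
  ids <- vapply(object@entries, function(e) e@modelId, character(1))
  if (anyDuplicated(ids)) {
    return(sprintf("duplicate model ids: %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (!identical(names(object@entries), unname(ids))) {
    return("entries must be named by their model ids")
  }
  for (e in object@entries) {
    if (!object@idEnvironment %in% names(e@predictions)) {
      return(sprintf("model '%s' lacks the ID environment '%s'",
                     e@modelId, object@idEnvironment))
    }
  }
  TRUE
})

#' Assemble a ModelGrid from entries
#'
#' Validates that model ids are unique and that every entry covers the
#' designated ID environment.
#'
#' @param entries List of [ModelEntry-class] objects.
#' @param idEnvironment The in-distribution environment id.
#' @return A validated [ModelGrid-class].
#' @export
assembleGrid <- function(entries, idEnvironment) {
  ids <- vapply(entries, function(e) e@modelId, character(1))
  if (anyDuplicated(ids)) {
    validationError(sprintf("duplicate model_id: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  for (e in entries) {
    if (!idEnvironment %in% names(e@predictions)) {
      validationError(sprintf("model '%s' lacks the ID environment '%s'",
                              e@modelId, idEnvironment))
    }
  }
  names(entries) <- ids
  new("ModelGrid", entries = entries, idEnvironment = idEnvironment)
}

# ---------------------------------------------------------------------------
# AuditConfig
# ---------------------------------------------------------------------------

#' AuditConfig: run configuration for the audit pipeline
#'
#' @slot tasks Character vector of task names.
#' @slot attributes Character vector of attribute names to audit.
#' @slot groupPairs Named list; for each attribute, the two designated group
#'   labels (`c(group1, group2)`) whose gap is reported.
#' @slot idEnvironment ID environment id.
#' @slot oodEnvironments OOD environment ids (possibly empty).
#' @slot alpha Significance level, in (0, 1).
#' @slot eceBins Number of equal-width calibration bins.
#' @slot nPerm Permutation count for MMD tests.
#' @slot nBoot Bootstrap resample count.
#' @slot performanceCutoff List with `type` (`"relative"` or `"absolute"`)
#'   and `margin` for the selection performance filter.
#' @slot seed Master seed.
#' @exportClass AuditConfig
setClass("AuditConfig",
  representation(
    tasks = "character", attributes = "character", groupPairs = "list",
    idEnvironment = "character", oodEnvironments = "character",
    alpha = "numeric", eceBins = "integer", nPerm = "integer",
    nBoot = "integer", performanceCutoff = "list", seed = "integer"
  )
)

setValidity("AuditConfig", function(object) {
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0, 1)")
  if (object@eceBins < 1L) return("eceBins must be >= 1")
  if (object@nPerm < 1L) return("nPerm must be >= 1")
  if (object@nBoot < 1L) return("nBoot must be >= 1")
  if (!object@performanceCutoff$type %in% c("relative", "absolute")) {
    return("performanceCutoff$type must be 'relative' or 'absolute'")
  }
  TRUE
})

#' Construct an AuditConfig
#'
#' @param tasks,attributes,groupPairs,idEnvironment,oodEnvironments See
#'   [AuditConfig-class].
#' @param alpha Significance level (default 0.05).
#' @param eceBins Calibration bins (default 10).
#' @param nPerm Permutations for MMD tests (default 1000).
#' @param nBoot Bootstrap resamples (default 1000).
#' @param performanceCutoff List with `type` and `margin`; default is the
#'   relative reading (keep models within 5 percent of the best reference
#'   model's validation AUROC).
#' @param seed Master seed (default 0).
#' @return An [AuditConfig-class].
#' @export
auditConfig <- function(tasks = character(), attributes = character(),
                        groupPairs = list(), idEnvironment = "id",
                        oodEnvironments = character(), alpha = 0.05,
                        eceBins = 10L, nPerm = 1000L, nBoot = 1000L,
                        performanceCutoff = list(type = "relative", margin = 0.05),
                        seed = 0L) {
  new("AuditConfig", tasks = tasks, attributes = attributes,
      groupPairs = groupPairs, idEnvironment = idEnvironment,
      oodEnvironments = oodEnvironments, alpha = alpha,
      eceBins = as.integer(eceBins), nPerm = as.integer(nPerm),
      nBoot = as.integer(nBoot), performanceCutoff = performanceCutoff,
      seed = as.integer(seed))
}
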