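#' @include AllClasses.R
NULL

#' Accessors for fairshift containers
#'
#' Small accessor family for the S4 containers: prefer these over direct slot
#' access.
#'
#' @param x A [PredictionSet-class], [EmbeddingSet-class],
#'   [ModelEntry-class] or [ModelGrid-class].
#' @param ... Further arguments for methods (`split`, `environment` filters).
#' @return See the individual generics.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("predScores", function(x, ...) standardGeneric("predScores"))

#' @rdname accessors
#' @export
setGeneric("predLabels", function(x, ...) standardGeneric("predLabels"))

#' @rdname accessors
#' @export
setGeneric("attrNames", function(x) standardGeneric("attrNames"))

#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x, attribute, ...) standardGeneric("groupLabels"))

#' @rdname accessors
#' @export
setGeneric("taskName", function(x) standardGeneric("taskName"))

#' @rdname accessors
#' @export
setGeneric("taskPolarity", function(x) standardGeneric("taskPolarity"))

#' @rdname accessors
#' @export
setGeneric("embMatrix", function(x, ...) standardGeneric("embMatrix"))

#' @rdname accessors
#' @export
setGeneric("sampleData", function(x, ...) standardGeneric("sampleData"))

#' @rdname accessors
#' @export
setGeneric("modelIds", function(x) standardGeneric("modelIds"))

#' @rdname accessors
#' @export
setGeneric("gridEntries", function(x) standardGeneric("gridEntries"))

#' @rdname accessors
#' @export
setGeneric("gridEntry", function(x, modelId) standardGeneric("gridEntry"))

#' @rdname accessors
#' @export
setGeneric("idEnvironment", function(x) standardGeneric("idEnvironment"))

#' @rdname accessors
#' @export
setGeneric("environmentNames", function(x) standardGeneric("environmentNames"))

#' Subset a PredictionSet or EmbeddingSet by split/environment
#'
#' @param x A [PredictionSet-class] or [EmbeddingSet-class].
#' @param split Optional split tag(s) to keep.
#' @param environment Optional environment id(s) to keep.
#' @return An object of the same class containing the matching rows.
#' @export
setGeneric("filterSamples", function(x, split = NULL, environment = NULL)
  standardGeneric("filterSamples"))

# ---------------------------------------------------------------------------
# PredictionSet methods
# ---------------------------------------------------------------------------

subsetIdx <- function(d, split, environment) {
  keep <- rep(TRUE, nrow(d))
  if (!is.null(split)) keep <- keep & d$split %in% split
  if (!is.null(environment)) keep <- keep & d$environment %in% environment
  keep
}

#' @rdname accessors
setMethod("sampleIds", "PredictionSet", function(x, split = NULL, environment = NULL) {
  x@data$sample_id[subsetIdx(x@data, split, environment)]
})

#' @rdname accessors
setMethod("predScores", "PredictionSet", function(x, split = NULL, environment = NULL) {
  x@data$score[subsetIdx(x@data, split, environment)]
})

#' @rdname accessors
setMethod("predLabels", "PredictionSet", function(x, split = NULL, environment = NULL) {
  x@data$label[subsetIdx(x@data, split, environment)]
})

#' @rdname accessors
setMethod("attrNames", "PredictionSet", function(x) x@attrNames)

#' @rdname accessors
setMethod("groupLabels", "PredictionSet",
  function(x, attribute, split = NULL, environment = NULL) {
    if (!attribute %in% x@attrNames) {
      validationError(sprintf("unknown attribute '%s' (have: %s)", attribute,
                              paste(x@attrNames, collapse = ", ")))
    }
    as.character(x@data[[attribute]][subsetIdx(x@data, split, environment)])
  })

#' @rdname accessors
setMethod("taskName", "PredictionSet", function(x) x@task)

#' @rdname accessors
setMethod("taskPolarity", "PredictionSet", function(x) x@taskPolarity)

#' @rdname accessors
setMethod("environmentNames", "PredictionSet", function(x) unique(x@data$environment))

setMethod("filterSamples", "PredictionSet", function(x, split = NULL, environment = NULL) {
  d <- x@data[subsetIdx(x@data, split, environment), , drop = FALSE]
  rownames(d) <- NULL
  initialize(x, data = d)
})

setMethod("show", "PredictionSet", function(object) {
  d <- object@data
  cat(sprintf("PredictionSet: task '%s' (%s), %d samples\n",
              object@task, object@taskPolarity, nrow(d)))
  if (nrow(d)) {
    cat(sprintf("  environments: %s\n", paste(unique(d$environment), collapse = ", ")))
    cat(sprintf("  splits: %s\n",
                paste(sprintf("%s=%d", names(table(d$split)), table(d$split)),
                      collapse = ", ")))
  }
  cat(sprintf("  attributes: %s\n", paste(object@attrNames, collapse = ", ")))
})

# ---------------------------------------------------------------------------
# EmbeddingSet methods
# ---------------------------------------------------------------------------

#' @rdname accessors
setMethod("sampleIds", "EmbeddingSet", function(x, split = NULL, environment = NULL) {
  x@sampleData$sample_id[subsetIdx(x@sampleData, split, environment)]
})

#' @rdname accessors
setMethod("embMatrix", "EmbeddingSet", function(x, split = NULL, environment = NULL) {
  x@embeddings[subsetIdx(x@sampleData, split, environment), , drop = FALSE]
})

#' @rdname accessors
setMethod("sampleData", "EmbeddingSet", function(x, split = NULL, environment = NULL) {
  x@sampleData[subsetIdx(x@sampleData, split, environment), , drop = FALSE]
})

#' @rdname accessors
setMethod("attrNames", "EmbeddingSet", function(x) x@attrNames)

#' @rdname accessors
setMethod("groupLabels", "EmbeddingSet",
  function(x, attribute, split = NULL, environment = NULL) {
    if (!attribute %in% x@attrNames) {
      validationError(sprintf("unknown attribute '%s'", attribute))
    }
    as.character(x@sampleData[[attribute]][subsetIdx(x@sampleData, split, environment)])
  })

setMethod("filterSamples", "EmbeddingSet", function(x, split = NULL, environment = NULL) {
  keep <- subsetIdx(x@sampleData, split, environment)
  sd <- x@sampleData[keep, , drop = FALSE]
  rownames(sd) <- NULL
  initialize(x, embeddings = x@embeddings[keep, , drop = FALSE], sampleData = sd)
})

setMethod("show", "EmbeddingSet", function(object) {
  cat(sprintf("EmbeddingSet: %d samples x %d dimensions\n",
              nrow(object@embeddings), ncol(object@embeddings)))
  cat(sprintf("  attributes: %s\n", paste(object@attrNames, collapse = ", ")))
})

# ---------------------------------------------------------------------------
# ModelEntry / ModelGrid methods
# ---------------------------------------------------------------------------

#' @rdname accessors
setMethod("environmentNames", "ModelEntry", function(x) names(x@predictions))

setMethod("show", "ModelEntry", function(object) {
  cat(sprintf("ModelEntry '%s' [%s | %s | seed %d]\n", object@modelId,
              object@algorithm, object@hparamTag, object@seed))
  cat(sprintf("  environments: %s\n", paste(names(object@predictions), collapse = ", ")))
  cat(sprintf("  embeddings: %s\n",
              if (length(object@embeddings)) paste(names(object@embeddings), collapse = ", ")
              else "none"))
})

#' @rdname accessors
setMethod("modelIds", "ModelGrid", function(x) names(x@entries))

#' @rdname accessors
setMethod("gridEntries", "ModelGrid", function(x) x@entries)

#' @rdname accessors
setMethod("gridEntry", "ModelGrid", function(x, modelId) {
  if (!modelId %in% names(x@entries)) {
    validationError(sprintf("no model '%s' in grid", modelId))
  }
  x@entries[[modelId]]
})

#' @rdname accessors
setMethod("idEnvironment", "ModelGrid", function(x) x@idEnvironment)

#' @rdname accessors
setMethod("environmentNames", "ModelGrid", function(x) {
  unique(unlist(lapply(x@entries, function(e) names(e@predictions)), use.names = FALSE))
})

setMethod("show", "ModelGrid", function(object) {
  algs <- table(vapply(object@entries, function(e) e@algorithm, character(1)))
  cat(sprintf("ModelGrid: %d models, ID environment '%s'\n",
              length(object@entries), object@idEnvironment))
  cat(sprintf("  environments: %s\n",
              paste(environmentNames(object), collapse = ", ")))
  cat(sprintf("  algorithms: %s\n",
              paste(sprintf("%s (%d)", names(algs), algs), collapse = ", ")))
})
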