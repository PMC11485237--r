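#' @include AllGenerics.R
NULL

#' Load a per-sample prediction table
#'
#' Reads a UTF-8 delimited text table with header columns `sample_id`,
#' `score`, `label`, `split`, `environment`, `task` plus one column per
#' demographic attribute. Rows with a missing value in any attribute column
#' are dropped and counted (mirroring the usual cohort rule of excluding
#' patients with missing demographics); rows with a missing score or label
#' are likewise dropped and counted. A non-missing score outside `[0, 1]` is
#' a validation error naming the offending row.
#'
#' @param path Path to the delimited file.
#' @param attributes Attribute column names. Default: every non-required
#'   column.
#' @param taskPolarity `"healthy_indicator"` or `"disease_indicator"`.
#' @param intersections Optional named list of attribute combinations to
#'   materialize as derived cross-product attributes, e.g.
#'   `list(sex_race = c("sex", "race"))` yields values like
#'   `"female White"`.
#' @param sep Field separator (default tab).
#' @return A validated [PredictionSet-class]. The number of dropped rows is
#'   attached as `attr(x, "droppedRows")` and reported via `message()`.
#' @export
loadPredictionTable <- function(path, attributes = NULL,
                                taskPolarity = "disease_indicator",
                                intersections = NULL, sep = "\t") {
  if (!file.exists(path)) validationError(sprintf("file not found: %s", path))
  d <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                  na.strings = c("NA", ""), check.names = FALSE)
  missingCols <- setdiff(REQUIRED_PRED_COLUMNS, names(d))
  if (length(missingCols)) {
    validationError(sprintf("missing required column(s): %s",
                            paste(missingCols, collapse = ", ")))
  }
  if (is.null(attributes)) attributes <- setdiff(names(d), REQUIRED_PRED_COLUMNS)

  bad <- which(!is.na(d$score) & (d$score < 0 | d$score > 1))
  if (length(bad)) {
    validationError(sprintf("score outside [0, 1] at row %s (value %s)",
                            bad[1L], format(d$score[bad[1L]])))
  }
  badLab <- which(!is.na(d$label) & !d$label %in% c(0, 1))
  if (length(badLab)) {
    validationError(sprintf("label not in {0, 1} at row %d", badLab[1L]))
  }

  keep <- !is.na(d$score) & !is.na(d$label)
  for (a in attributes) keep <- keep & !is.na(d[[a]])
  dropped <- sum(!keep)
  d <- d[keep, , drop = FALSE]
  rownames(d) <- NULL

  if (!is.null(intersections)) {
    for (nm in names(intersections)) {
      parts <- intersections[[nm]]
      d[[nm]] <- do.call(paste, d[parts])
      attributes <- union(attributes, nm)
    }
  }

  if (dropped > 0) {
    message(sprintf("loadPredictionTable: dropped %d row(s) with missing values", dropped))
  }
  ps <- predictionSet(d, attrNames = attributes, taskPolarity = taskPolarity)
  attr(ps, "droppedRows") <- dropped
  ps
}

#' Load an embedding matrix aligned to sample ids
#'
#' Accepts either delimited text (one row per sample, numeric columns, no
#' header) or a minimal binary format: two little-endian 32-bit integers
#' `(n, d)` followed by `n * d` little-endian float64 values in row-major
#' order.
#'
#' @param path Path to the matrix file.
#' @param ids Character vector of sample ids, one per expected row, in row
#'   order.
#' @param sampleData Optional data frame of per-sample annotations
#'   (`sample_id`, `split`, `environment`, attributes) matched to `ids`; if
#'   omitted a minimal annotation frame is fabricated.
#' @param format `"auto"`, `"text"` or `"binary"`.
#' @param sep Field separator for the text format.
#' @return A validated [EmbeddingSet-class] whose row order matches `ids`.
#' @export
loadEmbeddingMatrix <- function(path, ids, sampleData = NULL,
                                format = c("auto", "text", "binary"), sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) validationError(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(bin|f64)$", path)) "binary" else "text"
  }
  if (format == "binary") {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
    m <- matrix(readBin(con, "double", n = hdr[1L] * hdr[2L], size = 8L,
                        endian = "little"),
                nrow = hdr[1L], ncol = hdr[2L], byrow = TRUE)
  } else {
    fields <- utils::count.fields(path, sep = sep)
    if (length(unique(fields)) > 1L) {
      validationError(sprintf("ragged rows in embedding matrix: %d distinct widths",
                              length(unique(fields))))
    }
    m <- as.matrix(read.delim(path, sep = sep, header = FALSE))
    dimnames(m) <- NULL
  }
  if (nrow(m) != length(ids)) {
    validationError(sprintf("alignment error: %d matrix rows but %d ids",
                            nrow(m), length(ids)))
  }
  if (!all(is.finite(m))) validationError("embedding matrix contains non-finite values")
  if (is.null(sampleData)) {
    sampleData <- data.frame(sample_id = as.character(ids), split = "test",
                             environment = "env", stringsAsFactors = FALSE)
  } else {
    sampleData <- as.data.frame(sampleData, stringsAsFactors = FALSE)
    o <- match(as.character(ids), as.character(sampleData$sample_id))
    if (anyNA(o)) validationError("alignment error: ids missing from sampleData")
    sampleData <- sampleData[o, , drop = FALSE]
    rownames(sampleData) <- NULL
  }
  embeddingSet(m, sampleData)
}

# ---------------------------------------------------------------------------
# JSON reports
# ---------------------------------------------------------------------------

hasNaN <- function(x) {
  if (is.list(x)) return(any(vapply(x, hasNaN, logical(1))))
  is.numeric(x) && any(is.nan(x))
}

#' Write / read a JSON report
#'
#' Reports (lists or data frames produced by the audit functions) are
#' serialized as JSON with full numeric precision together with a provenance
#' block (package version, R version). `NaN` values are serialized as `null`
#' with a warning; `readReport()` returns the report component so that a
#' write/read cycle round-trips.
#'
#' @param report A list or data frame.
#' @param path Output path.
#' @param config Optional configuration echo stored alongside the report.
#' @return `writeReport()` returns `path` invisibly; `readReport()` the
#'   deserialized report.
#' @export
writeReport <- function(report, path, config = NULL) {
  if (hasNaN(report)) {
    warning("report contains NaN; serialized as null")
  }
  payload <- list(
    report = report,
    config = config,
    provenance = list(package = "fairshift",
                      version = as.character(utils::packageVersion("fairshift")),
                      r_version = paste(R.version$major, R.version$minor, sep = "."))
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  if (!file.exists(path)) validationError(sprintf("file not found: %s", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$report
}

# ---------------------------------------------------------------------------
# Grid serialization (the `simulate` CLI output format)
# ---------------------------------------------------------------------------

#' Write / load a ModelGrid as delimited text plus manifest
#'
#' `writeGrid()` lays a grid out as one prediction table and one embedding
#' table per (model, environment) plus a `manifest.json`; `loadGrid()`
#' reconstructs the [ModelGrid-class] from such a directory. The format is
#' plain text so grids can be produced or consumed by other tooling.
#'
#' @param grid A [ModelGrid-class].
#' @param dir Directory to write into / read from.
#' @return `writeGrid()` the directory (invisibly); `loadGrid()` a
#'   [ModelGrid-class].
#' @export
writeGrid <- function(grid, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(idEnvironment = idEnvironment(grid), models = list())
  for (e in gridEntries(grid)) {
    rec <- list(modelId = e@modelId, algorithm = e@algorithm,
                hparamTag = e@hparamTag, seed = e@seed,
                predictions = list(), embeddings = list())
    for (env in names(e@predictions)) {
      ps <- e@predictions[[env]]
      f <- sprintf("pred_%s_%s.tsv", e@modelId, env)
      d <- ps@data
      d$score <- formatC(d$score, digits = 17, format = "g")
      write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      rec$predictions[[env]] <- list(file = f, task = ps@task,
                                     taskPolarity = ps@taskPolarity,
                                     attributes = as.list(ps@attrNames))
    }
    for (env in names(e@embeddings)) {
      es <- e@embeddings[[env]]
      f <- sprintf("emb_%s_%s.tsv", e@modelId, env)
      m <- es@embeddings
      colnames(m) <- sprintf("e%d", seq_len(ncol(m)))
      out <- cbind(es@sampleData,
                   as.data.frame(apply(m, 2L, formatC, digits = 17, format = "g")))
      write.table(out, file.path(dir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      rec$embeddings[[env]] <- list(file = f, d = ncol(m),
                                    attributes = as.list(es@attrNames))
    }
    manifest$models[[e@modelId]] <- rec
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname writeGrid
#' @export
loadGrid <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) validationError(sprintf("no manifest.json in %s", dir))
  manifest <- jsonlite::read_json(mf)
  entries <- lapply(manifest$models, function(rec) {
    preds <- lapply(rec$predictions, function(p) {
      d <- read.delim(file.path(dir, p$file), sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
      d$sample_id <- as.character(d$sample_id)
      predictionSet(d, attrNames = unlist(p$attributes), task = p$task,
                    taskPolarity = p$taskPolarity)
    })
    embs <- lapply(rec$embeddings, function(p) {
      d <- read.delim(file.path(dir, p$file), sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
      dimCols <- sprintf("e%d", seq_len(p$d))
      embeddingSet(as.matrix(d[dimCols]),
                   d[setdiff(names(d), dimCols)],
                   attrNames = unlist(p$attributes))
    })
    modelEntry(rec$modelId, predictions = preds, embeddings = embs,
               algorithm = rec$algorithm, hparamTag = rec$hparamTag,
               seed = rec$seed)
  })
  assembleGrid(unname(entries), manifest$idEnvironment)
}
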