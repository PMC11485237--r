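#' @include selection.R decompose.R synthetic.R io.R
NULL

writeTsv <- function(d, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

gridDefaults <- function(grid) {
  e <- gridEntries(grid)[[1L]]
  ps <- e@predictions[[idEnvironment(grid)]]
  attribute <- attrNames(ps)[1L]
  groups <- sort(unique(groupLabels(ps, attribute)))
  list(attribute = attribute, groupPair = groups[1:2])
}

gridSettings <- function(grid, attribute, groupPair) {
  ood <- setdiff(environmentNames(grid), idEnvironment(grid))
  if (!length(ood)) return(NULL)
  data.frame(tarEnv = ood, attribute = attribute,
             group1 = groupPair[1L], group2 = groupPair[2L],
             stringsAsFactors = FALSE)
}

parseCliArgs <- function(args) {
  out <- list(positional = character())
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3L)
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        out[[key]] <- TRUE
        i <- i + 1L
      } else {
        out[[key]] <- args[i + 1L]
        i <- i + 2L
      }
    } else {
      out$positional <- c(out$positional, a)
      i <- i + 1L
    }
  }
  out
}

cliInt <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.integer(opts[[key]])
}

#' Command-line entry point
#'
#' In-process driver behind the `fairshift` command-line script
#' (`inst/scripts/fairshift`). Subcommands:
#' `simulate`, `audit`, `shift-test`, `probe`, `pareto`, `decompose`,
#' `select` — each a thin wrapper over the package functions, reading a
#' grid directory produced by `simulate` (or by [writeGrid()] on data
#' loaded from external prediction tables) and writing JSON/TSV outputs.
#' Common flags: `--grid <dir>`, `--out <dir>`, `--seed <int>`, and
#' subcommand-specific options (`--scenario`, `--attribute`, `--group1`,
#' `--group2`, `--nboot`, `--nperm`, `--cap`, `--model`, `--ntrain`,
#' `--nval`, `--ntest`).
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first).
#' @return Invisibly, an exit status: 0 on success, 2 on validation error.
#' @export
fairshiftCLI <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) {
      message("usage: fairshift <simulate|audit|shift-test|probe|pareto|decompose|select> [options]")
      return(invisible(2L))
    }
    cmd <- args[1L]
    opts <- parseCliArgs(args[-1L])
    seed <- cliInt(opts, "seed", 0L)
    outDir <- opts$out %||% "."
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    switch(cmd,
      "simulate" = cliSimulate(opts, outDir, seed),
      "audit" = cliAudit(opts, outDir, seed),
      "shift-test" = cliShiftTest(opts, outDir, seed),
      "probe" = cliProbe(opts, outDir),
      "pareto" = cliPareto(opts, outDir),
      "decompose" = cliDecompose(opts, outDir),
      "select" = cliSelect(opts, outDir, seed),
      validationError(sprintf("unknown subcommand '%s'", cmd))
    )
    0L
  }, fairshift_validation_error = function(e) {
    message("validation error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}

cliGrid <- function(opts) {
  if (is.null(opts$grid)) validationError("--grid <dir> is required")
  loadGrid(opts$grid)
}

cliSimulate <- function(opts, outDir, seed) {
  sc <- cannedScenarios(opts$scenario %||% "S3", seed = seed,
                        nTrain = cliInt(opts, "ntrain", 1000L),
                        nVal = cliInt(opts, "nval", 500L),
                        nTest = cliInt(opts, "ntest", 1000L))
  writeGrid(sc$grid, outDir)
  writeReport(list(scenario = sc$name, seed = seed,
                   attribute = sc$attribute,
                   groupPair = as.list(sc$groupPair),
                   models = length(modelIds(sc$grid)),
                   environments = as.list(environmentNames(sc$grid))),
              file.path(outDir, "simulate.json"))
}

cliAudit <- function(opts, outDir, seed) {
  grid <- cliGrid(opts)
  df <- gridDefaults(grid)
  attribute <- opts$attribute %||% df$attribute
  pair <- c(opts$group1 %||% df$groupPair[1L], opts$group2 %||% df$groupPair[2L])
  nBoot <- cliInt(opts, "nboot", 1000L)
  env <- opts$environment %||% idEnvironment(grid)
  perModel <- list()
  gapRows <- list()
  for (e in gridEntries(grid)) {
    ps <- e@predictions[[env]]
    gm <- groupMetrics(ps, attribute)
    gp <- gapCI(ps, attribute, pair, nBoot = nBoot,
                seed = deriveSeed(seed, match(e@modelId, modelIds(grid))))
    perModel[[e@modelId]] <- list(
      threshold = attr(gm, "threshold"), groups = gm,
      gap = gp[c("metric", "group1", "group2", "signedGap", "absGap",
                 "ciLow", "ciHigh", "significant")])
    gapRows[[e@modelId]] <- data.frame(
      modelId = e@modelId, algorithm = e@algorithm, metric = gp$metric,
      signedGap = gp$signedGap, absGap = gp$absGap,
      ciLow = gp$ciLow, ciHigh = gp$ciHigh,
      significant = gp$significant, stringsAsFactors = FALSE)
  }
  writeReport(list(environment = env, attribute = attribute,
                   groupPair = as.list(pair), models = perModel),
              file.path(outDir, "audit.json"),
              config = list(nBoot = nBoot, seed = seed))
  writeTsv(do.call(rbind, gapRows), file.path(outDir, "audit_gaps.tsv"))
}

cliShiftTest <- function(opts, outDir, seed) {
  grid <- cliGrid(opts)
  df <- gridDefaults(grid)
  attribute <- opts$attribute %||% df$attribute
  nPerm <- cliInt(opts, "nperm", 200L)
  cap <- cliInt(opts, "cap", 500L)
  withEmb <- Filter(function(e) idEnvironment(grid) %in% names(e@embeddings),
                    gridEntries(grid))
  if (!length(withEmb)) validationError("no model in the grid carries embeddings")
  e <- if (!is.null(opts$model)) gridEntry(grid, opts$model) else withEmb[[1L]]
  idEnv <- idEnvironment(grid)
  rep <- shiftReportID(e@predictions[[idEnv]], e@embeddings[[idEnv]],
                       attribute, nPerm = nPerm, seed = deriveSeed(seed, 1L),
                       subsampleCap = cap)
  rep$tarEnv <- NA_character_
  reports <- list(rep)
  oodEnvs <- setdiff(environmentNames(grid), idEnv)
  for (i in seq_along(oodEnvs)) {
    env <- oodEnvs[i]
    if (!env %in% names(e@predictions)) next
    r <- shiftReportOOD(e@predictions[[idEnv]], e@predictions[[env]],
                        e@embeddings[[idEnv]], e@embeddings[[env]],
                        attribute, nPerm = nPerm,
                        seed = deriveSeed(seed, 100L + i), subsampleCap = cap)
    r$tarEnv <- env
    reports[[length(reports) + 1L]] <- r
  }
  out <- do.call(rbind, reports)
  writeTsv(out, file.path(outDir, "shift_tests.tsv"))
  writeReport(as.data.frame(out), file.path(outDir, "shift_tests.json"),
              config = list(model = e@modelId, nPerm = nPerm,
                            subsampleCap = cap, seed = seed))
}

cliProbe <- function(opts, outDir) {
  grid <- cliGrid(opts)
  df <- gridDefaults(grid)
  attribute <- opts$attribute %||% df$attribute
  tbl <- encodeGrid(grid, attribute)
  writeTsv(tbl, file.path(outDir, "probe.tsv"))
  writeReport(tbl, file.path(outDir, "probe.json"),
              config = list(attribute = attribute))
}

cliPareto <- function(opts, outDir) {
  grid <- cliGrid(opts)
  df <- gridDefaults(grid)
  attribute <- opts$attribute %||% df$attribute
  pair <- c(opts$group1 %||% df$groupPair[1L], opts$group2 %||% df$groupPair[2L])
  envs <- environmentNames(grid)
  pts <- list()
  for (env in envs) {
    gs <- gridSummary(grid, env, attribute, pair)
    p <- paretoFront(data.frame(modelId = gs$modelId,
                                performance = gs$auroc, fairness = gs$absGap,
                                stringsAsFactors = FALSE))
    p$environment <- env
    pts[[env]] <- p
  }
  writeTsv(do.call(rbind, pts), file.path(outDir, "pareto_points.tsv"))
  oodEnvs <- setdiff(envs, idEnvironment(grid))
  if (length(oodEnvs)) {
    ft <- frontTransfer(grid, idEnvironment(grid), oodEnvs[1L], attribute, pair)
    writeTsv(ft, file.path(outDir, "front_transfer.tsv"))
  }
  writeReport(list(attribute = attribute, groupPair = as.list(pair),
                   environments = as.list(envs)),
              file.path(outDir, "pareto.json"))
}

cliDecompose <- function(opts, outDir) {
  grid <- cliGrid(opts)
  df <- gridDefaults(grid)
  attribute <- opts$attribute %||% df$attribute
  pair <- c(opts$group1 %||% df$groupPair[1L], opts$group2 %||% df$groupPair[2L])
  settings <- gridSettings(grid, attribute, pair)
  if (is.null(settings)) validationError("grid has no OOD environment to decompose")
  tbl <- decompositionTable(grid, settings)
  writeTsv(tbl, file.path(outDir, "decomposition.tsv"))
  writeReport(tbl, file.path(outDir, "decomposition.json"))
}

cliSelect <- function(opts, outDir, seed) {
  grid <- cliGrid(opts)
  df <- gridDefaults(grid)
  attribute <- opts$attribute %||% df$attribute
  pair <- c(opts$group1 %||% df$groupPair[1L], opts$group2 %||% df$groupPair[2L])
  settings <- gridSettings(grid, attribute, pair)
  if (is.null(settings)) validationError("grid has no OOD environment to select over")
  nBoot <- cliInt(opts, "nboot", 1000L)
  rep <- evaluateCriteria(grid, settings, nBoot = nBoot,
                          seed = deriveSeed(seed, 1L))
  alg <- perAlgorithmView(grid, settings, nBoot = nBoot,
                          seed = deriveSeed(seed, 2L))
  writeTsv(rep$perSetting, file.path(outDir, "selection_per_setting.tsv"))
  writeReport(list(
    criteria = list(perSetting = rep$perSetting, summary = rep$summary,
                    wilcoxon = as.data.frame(rep$wilcoxon)),
    algorithms = list(perSetting = alg$perSetting, summary = alg$summary,
                      wilcoxon = as.data.frame(alg$wilcoxon))),
    file.path(outDir, "selection.json"),
    config = list(nBoot = nBoot, seed = seed))
}

#' Run the full audit pipeline on a canned scenario
#'
#' Executes `simulate -> audit -> shift-test -> probe -> pareto ->
#' decompose -> select` through the CLI driver, writing everything under
#' `outDir`. All randomness derives from `seed`, so two runs with the same
#' seed produce byte-identical outputs.
#'
#' @param outDir Output directory.
#' @param scenario Canned scenario name (default `"S3"`).
#' @param seed Master seed.
#' @param nBoot Bootstrap resamples for audit/select.
#' @param nPerm Permutations for shift tests.
#' @return Invisibly, the output directory.
#' @export
runAuditPipeline <- function(outDir, scenario = "S3", seed = 0L,
                             nBoot = 1000L, nPerm = 200L) {
  gridDir <- file.path(outDir, "grid")
  steps <- list(
    c("simulate", "--scenario", scenario, "--out", gridDir, "--seed", seed),
    c("audit", "--grid", gridDir, "--out", file.path(outDir, "audit"),
      "--nboot", nBoot, "--seed", seed),
    c("shift-test", "--grid", gridDir, "--out", file.path(outDir, "shift"),
      "--nperm", nPerm, "--seed", seed),
    c("probe", "--grid", gridDir, "--out", file.path(outDir, "probe")),
    c("pareto", "--grid", gridDir, "--out", file.path(outDir, "pareto")),
    c("decompose", "--grid", gridDir, "--out", file.path(outDir, "decompose")),
    c("select", "--grid", gridDir, "--out", file.path(outDir, "select"),
      "--nboot", nBoot, "--seed", seed))
  for (s in steps) {
    status <- fairshiftCLI(as.character(s))
    if (!identical(status, 0L)) {
      validationError(sprintf("pipeline step '%s' failed with status %d",
                              s[1L], status))
    }
  }
  invisible(outDir)
}
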