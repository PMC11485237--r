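# Data model, file I/O and grid assembly.

writeTempTable <- function(d) {
  f <- tempfile(fileext = ".tsv")
  write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

basePredFrame <- function() {
  data.frame(
    sample_id = paste0("s", 1:4), score = c(0.1, 0.6, 0.8, 0.3),
    label = c(0, 1, 1, 0), split = "test", environment = "site_a",
    task = "disease", sex = c("female", "male", "female", "male"),
    race = c("White", "Black", "White", "Black"), stringsAsFactors = FALSE)
}

test_that("prediction tables load, drop missing-attribute rows, and reject bad scores", {
  f <- writeTempTable(basePredFrame())
  ps <- loadPredictionTable(f)
  expect_s4_class(ps, "PredictionSet")
  expect_length(sampleIds(ps), 4L)
  expect_identical(attr(ps, "droppedRows"), 0L)
  expect_setequal(attrNames(ps), c("sex", "race"))

  d <- basePredFrame()
  d$race[2] <- NA
  f <- writeTempTable(d)
  expect_message(ps <- loadPredictionTable(f), "dropped 1")
  expect_length(sampleIds(ps), 3L)
  expect_identical(attr(ps, "droppedRows"), 1L)

  d <- basePredFrame()
  d$score[3] <- 1.7
  f <- writeTempTable(d)
  expect_error(loadPredictionTable(f), "row 3", class = "fairshift_validation_error")

  d <- basePredFrame()
  names(d)[names(d) == "score"] <- "prob"
  f <- writeTempTable(d)
  expect_error(loadPredictionTable(f), "score", class = "fairshift_validation_error")
})

test_that("intersectional attributes are materialized at load time", {
  f <- writeTempTable(basePredFrame())
  ps <- loadPredictionTable(f, intersections = list(sex_race = c("sex", "race")))
  expect_true("sex_race" %in% attrNames(ps))
  expect_setequal(unique(groupLabels(ps, "sex_race")),
                  c("female White", "male Black"))
})

test_that("PredictionSet validity enforces ranges and id uniqueness", {
  d <- basePredFrame()
  expect_s4_class(predictionSet(d), "PredictionSet")
  d2 <- d
  d2$sample_id[2] <- "s1"
  expect_error(predictionSet(d2), "unique")
  d3 <- d
  d3$label[1] <- 2
  expect_error(predictionSet(d3), "label")
})

test_that("embedding matrices align to ids and reject ragged/NaN input", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("0.1\t0.2", "0.3\t0.4", "0.5\t0.6"), f)
  es <- loadEmbeddingMatrix(f, ids = c("a", "b", "c"))
  expect_s4_class(es, "EmbeddingSet")
  expect_identical(dim(embMatrix(es)), c(3L, 2L))
  expect_identical(sampleIds(es), c("a", "b", "c"))

  expect_error(loadEmbeddingMatrix(f, ids = c("a", "b")), "alignment",
               class = "fairshift_validation_error")

  writeLines(c("0.1\t0.2", "0.3", "0.5\t0.6"), f)
  expect_error(loadEmbeddingMatrix(f, ids = c("a", "b", "c")), "ragged",
               class = "fairshift_validation_error")

  writeLines(c("0.1\t0.2", "0.3\tNaN", "0.5\t0.6"), f)
  expect_error(loadEmbeddingMatrix(f, ids = c("a", "b", "c")), "finite",
               class = "fairshift_validation_error")
})

test_that("the binary embedding format round-trips through its header", {
  m <- matrix(rnorm(12), nrow = 3)
  f <- tempfile(fileext = ".bin")
  con <- file(f, "wb")
  writeBin(c(3L, 4L), con, size = 4L, endian = "little")
  writeBin(as.vector(t(m)), con, size = 8L, endian = "little")
  close(con)
  es <- loadEmbeddingMatrix(f, ids = c("a", "b", "c"))
  expect_equal(unname(embMatrix(es)), m)
})

test_that("grid assembly rejects duplicate ids and missing ID environments", {
  ps <- randPred(20, seed = 1)
  e1 <- modelEntry("m1", list(site_a = ps))
  e2 <- modelEntry("m2", list(site_a = ps))
  grid <- assembleGrid(list(e1, e2), "site_a")
  expect_identical(modelIds(grid), c("m1", "m2"))
  expect_error(assembleGrid(list(e1, e1), "site_a"), "duplicate",
               class = "fairshift_validation_error")
  e3 <- modelEntry("m3", list(site_b = randPred(20, 2, environment = "site_b")))
  expect_error(assembleGrid(list(e1, e3), "site_a"), "ID environment",
               class = "fairshift_validation_error")
})

test_that("JSON reports round-trip and NaN serializes as null with warning", {
  gap <- list(gap = -0.1, ci_low = -0.2, ci_high = 0.05,
              groups = c("female", "male"))
  f <- tempfile(fileext = ".json")
  writeReport(gap, f)
  back <- readReport(f)
  expect_equal(back$gap, gap$gap)
  expect_equal(back$groups, gap$groups)

  expect_warning(writeReport(list(x = NaN), f), "NaN")
  expect_null(readReport(f)$x)

  df <- data.frame(modelId = c("a", "b"), regret = c(0.1, 0))
  writeReport(df, f)
  expect_equal(readReport(f), df)
})

test_that("a grid written to disk reloads with identical metrics", {
  sc <- cannedScenarios("S1", seed = 3, nTrain = 60, nVal = 40, nTest = 80)
  small <- assembleGrid(gridEntries(sc$grid)[1:3], "site_a")
  dir <- tempfile()
  writeGrid(small, dir)
  back <- loadGrid(dir)
  expect_identical(modelIds(back), modelIds(small))
  g1 <- gridSummary(small, "site_a", "sex", c("female", "male"))
  g2 <- gridSummary(back, "site_a", "sex", c("female", "male"))
  expect_equal(g1$auroc, g2$auroc, tolerance = 1e-12)
  expect_equal(g1$signedGap, g2$signedGap, tolerance = 1e-12)
})

test_that("metrics are invariant to row permutation of the input table", {
  ps <- randPred(200, seed = 7)
  set.seed(8)
  perm <- sample.int(200)
  psPerm <- predictionSet(ps@data[perm, ], attrNames = "sex",
                          taskPolarity = "disease_indicator")
  expect_equal(
    aurocScore(predScores(ps), predLabels(ps)),
    aurocScore(predScores(psPerm), predLabels(psPerm)))
  g1 <- fairnessGap(ps, "sex", c("female", "male"))
  g2 <- fairnessGap(psPerm, "sex", c("female", "male"))
  expect_equal(g1$signedGap, g2$signedGap)
  expect_equal(g1$threshold, g2$threshold)
  m1 <- groupMetrics(ps, "sex")
  m2 <- groupMetrics(psPerm, "sex")
  expect_equal(m1, m2, ignore_attr = TRUE)
})
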