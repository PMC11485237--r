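# Pareto fronts, correlation utilities and grid-level analyses.

test_that("Pareto front equals the O(n^2) dominance oracle and ignores order", {
  pts <- data.frame(modelId = c("a", "b"), performance = c(0.8, 0.7),
                    fairness = c(0.1, 0.2))
  expect_equal(paretoFront(pts)$onFront, c(TRUE, FALSE))
  # identical points all stay on the front
  same <- data.frame(modelId = letters[1:3], performance = 0.8, fairness = 0.1)
  expect_true(all(paretoFront(same)$onFront))
  for (case in 1:30) {
    set.seed(500 + case)
    n <- sample(5:200, 1)
    pts <- data.frame(modelId = sprintf("m%03d", 1:n),
                      performance = round(runif(n), 2),
                      fairness = round(runif(n), 2))
    got <- paretoFront(pts)$onFront
    expect_identical(got, paretoDominanceOracle(pts$performance, pts$fairness))
    perm <- sample.int(n)
    gotPerm <- paretoFront(pts[perm, ])$onFront
    expect_identical(gotPerm, got[perm])
  }
})

test_that("constrained best fairness honors the floor and tie rules", {
  pts <- data.frame(modelId = c("a", "b"), performance = c(0.85, 0.75),
                    fairness = c(0.05, 0.01))
  expect_equal(constrainedBestFairness(pts, 0.8)$modelId, "a")
  expect_equal(constrainedBestFairness(pts, 0.5)$modelId, "b")
  expect_error(constrainedBestFairness(pts, 0.95), "0.85",
               class = "fairshift_validation_error")
  ties <- data.frame(modelId = c("b", "a", "c"), performance = c(0.8, 0.9, 0.9),
                     fairness = c(0.1, 0.1, 0.1))
  expect_equal(constrainedBestFairness(ties, 0)$modelId, "a")
  # a unique constrained optimum lies on the Pareto front
  set.seed(99)
  pts <- data.frame(modelId = sprintf("m%02d", 1:50),
                    performance = runif(50), fairness = runif(50))
  best <- constrainedBestFairness(pts, 0.5)
  front <- paretoFront(pts)
  expect_true(front$onFront[front$modelId == best$modelId])
})

test_that("Pearson r, p and Fisher-z CI match the closed forms", {
  x <- 1:10
  expect_equal(pearsonWithCI(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonWithCI(x, -x)$r, -1)
  set.seed(77)
  a <- rnorm(10)
  b <- rnorm(10)
  out <- pearsonWithCI(a, b)
  rHand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(out$r, rHand, tolerance = 1e-12)
  tHand <- rHand * sqrt(8 / (1 - rHand^2))
  expect_equal(out$p.value, 2 * pt(-abs(tHand), df = 8), tolerance = 1e-12)
  zHand <- atanh(rHand) + c(-1, 1) * qnorm(0.975) / sqrt(7)
  expect_equal(c(out$ciLow, out$ciHigh), tanh(zHand), tolerance = 1e-10)
  expect_error(pearsonWithCI(rep(1, 5), rnorm(5)), "variance",
               class = "fairshift_validation_error")
})

test_that("the encoding-fairness correlation applies the 0.7 AUROC floor exactly", {
  enc <- data.frame(modelId = sprintf("m%d", 1:6),
                    probeAuroc = c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95))
  gap <- data.frame(modelId = sprintf("m%d", 1:6),
                    absGap = c(0.01, 0.05, 0.1, 0.2, 0.3, 0.32))
  perf <- data.frame(modelId = sprintf("m%d", 1:6),
                     auroc = c(0.65, 0.69, 0.7, 0.75, 0.8, 0.85))
  out <- encodingFairnessCorrelation(enc, gap, perf)
  expect_equal(out$nExcluded, 2L)  # the two models below 0.7
  expect_equal(out$n, 4L)
  constant <- transform(enc, probeAuroc = 0.8)
  expect_error(encodingFairnessCorrelation(constant, gap, perf), "variance",
               class = "fairshift_validation_error")
})

test_that("transfer correlation is exactly 1 when OOD mirrors ID", {
  sc <- cannedScenarios("S1", seed = 5, nTrain = 80, nVal = 60, nTest = 100)
  # clone the ID environment under a second name
  entries <- lapply(gridEntries(sc$grid)[1:6], function(e) {
    psB <- e@predictions$site_a
    psB@data$environment <- "site_b"
    e@predictions$site_b <- psB
    e
  })
  grid <- assembleGrid(entries, "site_a")
  tp <- transferCorrelation(grid, "site_a", "site_b", "performance",
                            attribute = "sex", groupPair = c("female", "male"))
  tf <- transferCorrelation(grid, "site_a", "site_b", "fairness",
                            attribute = "sex", groupPair = c("female", "male"))
  expect_equal(tp$r, 1, tolerance = 1e-9)
  expect_equal(tf$r, 1, tolerance = 1e-9)
  expect_equal(tp$n, 6L)
  ft <- frontTransfer(grid, "site_a", "site_b", "sex", c("female", "male"))
  expect_identical(ft$onFrontID, ft$onFrontOOD)
  # membership flags agree with a direct dominance recount
  expect_identical(ft$onFrontID,
                   paretoDominanceOracle(ft$performanceID, ft$fairnessID))
})
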