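# Per-group performance, calibration and fairness-gap metrics.

test_that("AUROC equals exhaustive pair counting, including ties", {
  expect_equal(aurocScore(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(aurocScore(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(aurocScore(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_true(is.na(aurocScore(runif(5), rep(1, 5))))
  for (case in 1:40) {
    set.seed(case)
    n <- sample(4:50, 1)
    s <- round(runif(n), 2)  # rounding forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_equal(aurocScore(s, y), aurocPairOracle(s, y), tolerance = 1e-12)
  }
})

test_that("F1 threshold maximizes F1 over observed scores, smallest on ties", {
  expect_equal(f1OptimalThreshold(c(0.2, 0.6, 0.9), c(0, 1, 1)), 0.6)
  # all positive: predicting everything positive is optimal -> smallest score
  expect_equal(f1OptimalThreshold(c(0.3, 0.7, 0.5), c(1, 1, 1)), 0.3)
  expect_error(f1OptimalThreshold(c(0.3, 0.7), c(0, 0)),
               class = "fairshift_validation_error")
  for (case in 1:60) {
    set.seed(100 + case)
    n <- sample(3:60, 1)
    s <- round(runif(n), 2)
    y <- rbinom(n, 1, 0.5)
    if (!any(y == 1)) y[1] <- 1
    expect_equal(f1OptimalThreshold(s, y), f1SweepOracle(s, y))
  }
})

test_that("confusion rates follow the score >= threshold rule with NA markers", {
  cr <- confusionRates(c(0.9, 0.1), c(1, 0), 0.5)
  expect_equal(cr[c("tpr", "tnr", "fpr", "fnr")],
               list(tpr = 1, tnr = 1, fpr = 0, fnr = 0))
  cr <- confusionRates(c(0.9, 0.1), c(0, 1), 0.5)
  expect_equal(cr$fpr, 1)
  expect_equal(cr$fnr, 1)
  cr <- confusionRates(c(0.2, 0.6), c(0, 0), 0.5)
  expect_true(is.na(cr$tpr) && is.na(cr$fnr))
  expect_equal(cr$fpr, 0.5)
  # boundary: score equal to threshold counts as positive
  expect_equal(confusionRates(0.5, 1, 0.5)$tpr, 1)
})

test_that("TPR + FNR = 1 and TNR + FPR = 1 wherever defined", {
  for (case in 1:20) {
    set.seed(200 + case)
    s <- runif(30)
    y <- rbinom(30, 1, 0.5)
    cr <- confusionRates(s, y, runif(1))
    if (!is.na(cr$tpr)) expect_equal(cr$tpr + cr$fnr, 1)
    if (!is.na(cr$tnr)) expect_equal(cr$tnr + cr$fpr, 1)
  }
})

test_that("ECE matches direct bin accounting and its closed cases", {
  expect_equal(eceScore(rep(0.7, 10), c(rep(1, 7), rep(0, 3)), 10), 0)
  expect_equal(eceScore(rep(0.9, 5), rep(0, 5), 10), 0.9)
  for (case in 1:20) {
    set.seed(300 + case)
    s <- runif(20)
    y <- rbinom(20, 1, s)
    expect_equal(eceScore(s, y, 10), eceBinOracle(s, y, 10), tolerance = 1e-12)
    expect_equal(eceScore(s, y, 7), eceBinOracle(s, y, 7), tolerance = 1e-12)
  }
  # a score of exactly 1 lands in the (right-closed) final bin
  expect_equal(eceScore(c(1, 1), c(1, 1), 10), 0)
})

test_that("group metrics share one threshold and pool to the full counts", {
  set.seed(42)
  n <- 400
  s <- runif(n)
  y <- rbinom(n, 1, s)
  g <- rep(c("female", "male"), n / 2)
  ps <- makePred(s, y, g)
  gm <- groupMetrics(ps, "sex")
  thr <- attr(gm, "threshold")
  expect_equal(thr, f1OptimalThreshold(s, y))
  # pooled counts = size-weighted combination of per-group counts
  crAll <- confusionRates(s, y, thr)
  perGroup <- lapply(unique(g), function(gr) confusionRates(s[g == gr], y[g == gr], thr))
  expect_equal(crAll$tp, sum(vapply(perGroup, `[[`, numeric(1), "tp")))
  expect_equal(crAll$fp, sum(vapply(perGroup, `[[`, numeric(1), "fp")))
  # identical score/label distributions in both groups -> identical rates
  s2 <- rep(s[1:100], 2)
  y2 <- rep(y[1:100], 2)
  g2 <- rep(c("female", "male"), each = 100)
  gm2 <- groupMetrics(makePred(s2, y2, g2), "sex")
  expect_equal(gm2$fnr[1], gm2$fnr[2])
  expect_equal(gm2$auroc[1], gm2$auroc[2])
})

test_that("fairness gap has the polarity-selected metric and signed/abs relation", {
  s <- c(0.9, 0.9, 0.1, 0.1, 0.9, 0.1, 0.1, 0.1)
  y <- c(0, 1, 0, 1, 0, 1, 0, 1)
  g <- rep(c("female", "male"), each = 4)
  psDis <- makePred(s, y, g, taskPolarity = "disease_indicator")
  psHea <- makePred(s, y, g, taskPolarity = "healthy_indicator")
  gd <- fairnessGap(psDis, "sex", c("female", "male"), threshold = 0.5)
  gh <- fairnessGap(psHea, "sex", c("female", "male"), threshold = 0.5)
  expect_equal(gd$metric, "fnr")
  expect_equal(gh$metric, "fpr")
  expect_equal(gd$absGap, abs(gd$signedGap))
  # overdiagnosis flag swaps to the complementary rate
  gdo <- fairnessGap(psDis, "sex", c("female", "male"), threshold = 0.5,
                     overdiagnosis = TRUE)
  expect_equal(gdo$metric, "fpr")
  expect_equal(gdo$signedGap, gh$signedGap)
  # identical groups give zero gap
  ps0 <- makePred(rep(s[1:4], 2), rep(y[1:4], 2), rep(c("female", "male"), each = 4))
  expect_equal(fairnessGap(ps0, "sex", c("female", "male"), threshold = 0.5)$signedGap, 0)
})

test_that("gap bootstrap CI is seed-deterministic with zero width on constant data", {
  ps <- randPred(300, seed = 11)
  a <- gapCI(ps, "sex", c("female", "male"), nBoot = 200, seed = 5)
  b <- gapCI(ps, "sex", c("female", "male"), nBoot = 200, seed = 5)
  expect_identical(a$ciLow, b$ciLow)
  expect_identical(a$ciHigh, b$ciHigh)
  expect_true(a$ciLow <= a$signedGap && a$signedGap <= a$ciHigh)
  # constant data: every resample yields the same gap
  psC <- makePred(rep(c(0.9, 0.1), 50), rep(c(1, 0), 50),
                  rep(c("female", "male"), each = 50))
  cc <- gapCI(psC, "sex", c("female", "male"), nBoot = 100, seed = 1)
  expect_equal(cc$ciLow, cc$ciHigh)
  expect_equal(cc$ciLow, 0)
})

test_that("rebalancing equalizes cell sizes and prevalences exactly", {
  set.seed(9)
  sizes <- c(10, 10, 10, 40)
  cells <- list(c("female", "young"), c("female", "old"),
                c("male", "young"), c("male", "old"))
  rows <- do.call(rbind, lapply(1:4, function(i) {
    n <- sizes[i]
    data.frame(score = runif(n), label = rep(c(0, 1), length.out = n),
               sex = cells[[i]][1], age = cells[[i]][2],
               stringsAsFactors = FALSE)
  }))
  ps <- makePred(rows$score, rows$label, rows$sex)
  ps@data$age <- rows$age
  ps@attrNames <- c("sex", "age")
  rb <- rebalanceEvalSet(ps, c("sex", "age"), seed = 2)
  d <- rb@data
  tab <- table(d$sex, d$age)
  expect_true(all(tab == 10))
  prev <- as.vector(tapply(d$label, paste(d$sex, d$age), mean))
  expect_equal(prev, rep(prev[1], 4))
  # empty (cell, class) is an error naming the cell
  psBad <- makePred(runif(20), rep(1, 20), rep(c("female", "male"), 10))
  expect_error(rebalanceEvalSet(psBad, "sex"), "empty",
               class = "fairshift_validation_error")
})

test_that("percentile bootstrap helper is deterministic and degenerate on constants", {
  x <- rep(2.5, 40)
  ci <- bootstrapCI(x, mean, nBoot = 200, seed = 3)
  expect_equal(ci$ciLow, 2.5)
  expect_equal(ci$ciHigh, 2.5)
  set.seed(1)
  y <- rnorm(50)
  a <- bootstrapCI(y, mean, nBoot = 300, seed = 7)
  b <- bootstrapCI(y, mean, nBoot = 300, seed = 7)
  expect_identical(a, b)
})
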