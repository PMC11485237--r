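# Synthetic cohort generator and its closed-form oracle.

twoEnvScenario <- function(kappaA = 1.5, kappaB = 0, rhoA = c(0.35, 0.2)) {
  syntheticScenario(list(
    site_a = list(pi = c(0.5, 0.5), rho = rhoA, kappa = kappaA),
    site_b = list(pi = c(0.5, 0.5), rho = c(0.25, 0.25), kappa = kappaB)))
}

test_that("environment sampling is seed-deterministic and matches declared rates", {
  sc <- twoEnvScenario()
  a <- sampleEnvironment(sc, "site_a", 500, seed = 1)
  b <- sampleEnvironment(sc, "site_a", 500, seed = 1)
  expect_identical(a, b)
  expect_error(sampleEnvironment(sc, "nowhere", 10), "unknown",
               class = "fairshift_validation_error")
  big <- sampleEnvironment(sc, "site_a", 10000, seed = 2)
  for (i in 1:2) {
    gr <- sc$groups[i]
    prev <- mean(big$Y[big$A == gr])
    se <- sqrt(0.35 * 0.65 / sum(big$A == gr))
    expect_lt(abs(prev - sc$environments$site_a$rho[i]), 3 * se + 0.02)
  }
  # kappa = 0: group means of z coincide (attribute axis carries no signal)
  nul <- sampleEnvironment(sc, "site_b", 8000, seed = 3)
  diffV <- mean(nul$linV[nul$A == "female"]) - mean(nul$linV[nul$A == "male"])
  expect_lt(abs(diffV), 3 * sqrt(2 / 4000))
})

test_that("model scores are monotone in the linear score and polarity-correct", {
  sc <- twoEnvScenario()
  m <- syntheticModel(theta = 0.3, gamma = 2, b = -0.5)
  smp <- sampleEnvironment(sc, "site_a", 300, seed = 4)
  out <- scoreModel(m, smp)
  expect_true(all(out$score > 0 & out$score < 1))
  expect_identical(order(out$score), order(out$linear))
  # theta = 0: score depends on z only through the disease axis
  m0 <- syntheticModel(theta = 0)
  out0 <- scoreModel(m0, smp)
  expect_equal(out0$linear, smp$linU)
  # theta = pi/2: only the attribute axis
  m90 <- syntheticModel(theta = pi / 2)
  expect_equal(scoreModel(m90, smp)$linear, smp$linV, tolerance = 1e-12)
})

test_that("closed-form rates have the right symmetries and limits", {
  sc <- twoEnvScenario()
  m0 <- syntheticModel(theta = 0)
  r0 <- analyticGroupRates(sc, "site_a", m0, threshold = 0.6)
  expect_equal(r0$fpr[1], r0$fpr[2])  # no shortcut -> equal rates
  expect_equal(r0$fnr[1], r0$fnr[2])
  m <- syntheticModel(theta = 0.5)
  rHi <- analyticGroupRates(sc, "site_a", m, threshold = 50)
  expect_true(all(rHi$fpr < 1e-6) && all(rHi$fnr > 1 - 1e-6))
  # the model-noise term widens the effective scale
  mN <- syntheticModel(theta = 0.5, noiseSd = 1)
  rN <- analyticGroupRates(sc, "site_a", mN, threshold = 1.5)
  expect_true(all(rN$fpr > analyticGroupRates(sc, "site_a", m, 1.5)$fpr))
})

test_that("empirical group rates recover the Phi formulas", {
  sc <- twoEnvScenario()
  m <- syntheticModel(theta = 0.45)
  smp <- sampleEnvironment(sc, "site_a", 6000, seed = 5)
  lin <- scoreModel(m, smp)$linear
  t <- 0.7
  exp_ <- analyticGroupRates(sc, "site_a", m, t)
  for (i in 1:2) {
    gr <- sc$groups[i]
    neg <- smp$A == gr & smp$Y == 0
    pos <- smp$A == gr & smp$Y == 1
    fprHat <- mean(lin[neg] >= t)
    fnrHat <- mean(lin[pos] < t)
    seF <- sqrt(exp_$fpr[i] * (1 - exp_$fpr[i]) / sum(neg))
    seN <- sqrt(exp_$fnr[i] * (1 - exp_$fnr[i]) / sum(pos))
    expect_lt(abs(fprHat - exp_$fpr[i]), 4 * seF)
    expect_lt(abs(fnrHat - exp_$fnr[i]), 4 * seN)
  }
})

test_that("the model zoo validates, is deterministic, and gaps grow with theta", {
  sc <- twoEnvScenario(kappaA = 2.0, rhoA = c(0.5, 0.1))
  models <- lapply(seq(0, 0.9, length.out = 6), function(th) {
    syntheticModel(theta = th, b = -0.75 * cos(th),
                   modelId = sprintf("m_t%03.0f", th * 100))
  })
  grid <- makeModelZoo(sc, models, nTrain = 100, nVal = 80, nTest = 400, seed = 8)
  expect_s4_class(grid, "ModelGrid")
  expect_equal(length(modelIds(grid)), 6L)
  grid2 <- makeModelZoo(sc, models, nTrain = 100, nVal = 80, nTest = 400, seed = 8)
  expect_identical(gridSummary(grid, "site_a", "sex", c("female", "male")),
                   gridSummary(grid2, "site_a", "sex", c("female", "male")))
  gs <- gridSummary(grid, "site_a", "sex", c("female", "male"))
  rho <- cor(seq(0, 0.9, length.out = 6), gs$absGap, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("canned scenarios expose the documented structure", {
  s1 <- cannedScenarios("S1", seed = 9, nTrain = 40, nVal = 30, nTest = 40)
  expect_null(s1$settings)
  expect_equal(environmentNames(s1$grid), "site_a")
  expect_equal(length(modelIds(s1$grid)), 24L)
  s3 <- cannedScenarios("S3", seed = 9, nTrain = 40, nVal = 30, nTest = 40)
  expect_equal(nrow(s3$settings), 12L)
  expect_equal(idEnvironment(s3$grid), "site_a")
  expect_length(environmentNames(s3$grid), 13L)
  algs <- vapply(gridEntries(s3$grid), function(e) e@algorithm, character(1))
  expect_setequal(unique(algs), c("debiased-like", "erm-like"))
})
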