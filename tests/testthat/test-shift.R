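# Distribution-shift distances and two-sample tests.

test_that("Bernoulli TV distance is |p1 - p2| and symmetric", {
  expect_equal(tvDistanceBinary(0.3, 0.5), 0.2)
  expect_equal(tvDistanceBinary(0.7, 0.7), 0)
  set.seed(1)
  p <- runif(20)
  q <- runif(20)
  expect_equal(tvDistanceBinary(p, q), tvDistanceBinary(q, p))
})

test_that("pooled z proportion test matches the hand-computed statistic", {
  expect_equal(binomialProportionTest(50, 100, 50, 100)$p.value, 1)
  bt <- binomialProportionTest(5, 10, 9, 10)
  zHand <- (0.5 - 0.9) / sqrt(0.7 * 0.3 * (1 / 10 + 1 / 10))
  expect_equal(bt$statistic, zHand, tolerance = 1e-12)
  expect_equal(bt$p.value, 2 * pnorm(-abs(zHand)), tolerance = 1e-12)
  expect_equal(round(bt$p.value, 3), 0.051)
  # degenerate pooled proportion
  expect_equal(binomialProportionTest(0, 5, 0, 8)$p.value, 1)
  expect_error(binomialProportionTest(1, 0, 1, 2))
  # the Fisher variant is available and agrees qualitatively
  expect_lt(binomialProportionTest(1, 50, 20, 50, exact = TRUE)$p.value, 0.001)
})

test_that("proportion-test p-values are roughly uniform under the null", {
  set.seed(21)
  p <- replicate(600, {
    k1 <- rbinom(1, 200, 0.3)
    k2 <- rbinom(1, 200, 0.3)
    binomialProportionTest(k1, 200, k2, 200)$p.value
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)
})

test_that("unbiased MMD^2 matches the double-loop kernel-sum oracle", {
  for (case in 1:10) {
    set.seed(400 + case)
    X1 <- matrix(rnorm(sample(8:20, 1) * 3), ncol = 3)
    X2 <- matrix(rnorm(sample(8:20, 1) * 3, mean = 0.5), ncol = 3)
    v <- mmd2(X1, X2)
    expect_equal(as.numeric(v), mmd2LoopOracle(X1, X2, attr(v, "sigma")),
                 tolerance = 1e-10)
  }
  expect_error(mmd2(matrix(0, 3, 2), matrix(0, 3, 3)), "dimension",
               class = "fairshift_validation_error")
})

test_that("MMD^2 is near zero for identical distributions, large for separated ones", {
  set.seed(5)
  X <- matrix(rnorm(200 * 4), ncol = 4)
  near <- mmd2(X[1:100, ], X[101:200, ])
  far <- mmd2(X[1:100, ], X[101:200, ] + 3)
  expect_lt(abs(near), 0.05)
  expect_gt(far, 0.5)
})

test_that("MMD permutation test is seed-deterministic with the add-one floor", {
  set.seed(6)
  X1 <- matrix(rnorm(60 * 2), ncol = 2)
  X2 <- matrix(rnorm(60 * 2, mean = 2), ncol = 2)
  a <- mmdPermutationTest(X1, X2, nPerm = 99, seed = 3)
  b <- mmdPermutationTest(X1, X2, nPerm = 99, seed = 3)
  expect_identical(a$p.value, b$p.value)
  expect_equal(a$p.value, 1 / 100)  # strong separation floors at 1/(1+nPerm)
  expect_gte(a$p.value, 1 / (1 + 99))
  # power: 1-SD mean shift at d = 8, n = 200 rejects essentially always
  set.seed(7)
  Y1 <- matrix(rnorm(200 * 8), ncol = 8)
  Y2 <- matrix(rnorm(200 * 8, mean = 1), ncol = 8)
  expect_lt(mmdPermutationTest(Y1, Y2, nPerm = 200, seed = 1)$p.value, 0.05)
})

test_that("Bonferroni adjustment is min(1, m p) with ordering preserved", {
  expect_equal(bonferroniAdjust(c(0.01, 0.2)), c(0.02, 0.4))
  expect_equal(bonferroniAdjust(c(0.5, 0.9)), c(1, 1))
  expect_equal(bonferroniAdjust(0.03), 0.03)
  p <- runif(10)
  expect_true(all(bonferroniAdjust(p) >= p))
})

makeEmb <- function(ps, shiftBy = 0) {
  n <- length(sampleIds(ps))
  set.seed(1000 + n)
  sd <- ps@data[c("sample_id", "split", "environment", "sex")]
  embeddingSet(matrix(rnorm(n * 4), ncol = 4) + shiftBy, sd)
}

test_that("ID shift report enumerates group pairs with one Bonferroni family", {
  set.seed(31)
  n <- 90
  g <- sample(c("a", "b", "c"), n, replace = TRUE)
  ps <- makePred(runif(n), rbinom(n, 1, 0.3), g, attribute = "sex")
  rep <- shiftReportID(ps, makeEmb(ps), "sex", nPerm = 50, seed = 1)
  expect_equal(nrow(rep), 6L)  # 3 pairs x 2 shift kinds
  expect_equal(rep$p.adjusted, pmin(1, 6 * rep$p.value))
  expect_true(all(rep$p.adjusted >= rep$p.value))
})

test_that("ID prevalence shift is detected at 0.2 vs 0.5 and n = 500", {
  set.seed(32)
  g <- rep(c("female", "male"), each = 500)
  y <- c(rbinom(500, 1, 0.2), rbinom(500, 1, 0.5))
  ps <- makePred(runif(1000), y, g)
  rep <- shiftReportID(ps, makeEmb(ps), "sex", nPerm = 50, seed = 2)
  prevRow <- rep[rep$kind == "prevalence P(Y|A)", ]
  expect_lt(prevRow$p.adjusted, 0.05)
  expect_equal(prevRow$distance, abs(mean(y[1:500]) - mean(y[501:1000])))
})

test_that("OOD shift report covers label/covariate plus per-group tests", {
  set.seed(33)
  psS <- makePred(runif(120), rbinom(120, 1, 0.3),
                  rep(c("female", "male"), 60), environment = "src")
  psT <- makePred(runif(120), rbinom(120, 1, 0.3),
                  rep(c("female", "male"), 60), environment = "tar")
  rep <- shiftReportOOD(psS, psT, makeEmb(psS), makeEmb(psT), "sex",
                        nPerm = 50, seed = 3)
  expect_equal(nrow(rep), 6L)  # 2 pooled + 2 groups x 2 kinds
  expect_setequal(unique(rep$kind),
                  c("label P(Y)", "covariate P(X)", "prevalence P(Y|A=a)",
                    "representation P(X|A=a)"))
  # src = tar: all distances ~ 0
  repSame <- shiftReportOOD(psS, psS, makeEmb(psS), makeEmb(psS), "sex",
                            nPerm = 50, seed = 4)
  expect_true(all(abs(repSame$distance) < 0.05))
})
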