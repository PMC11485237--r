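#' @include AllGenerics.R
NULL

#' Total variation distance between two Bernoulli distributions
#'
#' For binary outcomes the total variation distance between Bernoulli(p1)
#' and Bernoulli(p2) reduces to `|p1 - p2|`.
#'
#' @param p1,p2 Proportions in `[0, 1]`.
#' @return The distance in `[0, 1]`.
#' @export
tvDistanceBinary <- function(p1, p2) {
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  abs(p1 - p2)
}

#' Two-sample binomial proportion test (pooled z)
#'
#' Two-sided test of H0: p1 = p2 using the pooled two-proportion z statistic
#' without continuity correction. When the pooled proportion is 0 or 1 the
#' statistic is degenerate and p = 1 is returned. An exact alternative
#' (Fisher) is available via `exact = TRUE`.
#'
#' @param k1,n1 Successes and trials in sample 1.
#' @param k2,n2 Successes and trials in sample 2.
#' @param exact Use Fisher's exact test instead of the pooled z.
#' @return List with `p1`, `p2`, `statistic` (z; `NA` for exact), `p.value`.
#' @export
#' @examples
#' binomialProportionTest(5, 10, 9, 10)$p.value # ~0.051
binomialProportionTest <- function(k1, n1, k2, n2, exact = FALSE) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1
  p2 <- k2 / n2
  if (exact) {
    p <- stats::fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2))$p.value
    return(list(p1 = p1, p2 = p2, statistic = NA_real_, p.value = p))
  }
  pooled <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  if (se == 0) {
    return(list(p1 = p1, p2 = p2, statistic = 0, p.value = 1))
  }
  z <- (p1 - p2) / se
  list(p1 = p1, p2 = p2, statistic = z, p.value = 2 * pnorm(-abs(z)))
}

medianHeuristicSigma <- function(D2) {
  off <- D2[upper.tri(D2)]
  s <- sqrt(stats::median(off))
  if (!is.finite(s) || s <= 0) 1 else s
}

rbfFromD2 <- function(D2, sigma) exp(-D2 / (2 * sigma^2))

squaredDistanceMatrix <- function(X) {
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  D2
}

#' Unbiased squared maximum mean discrepancy
#'
#' U-statistic estimator of the squared MMD between two samples under an RBF
#' kernel; the bandwidth defaults to the median heuristic on the pooled
#' pairwise Euclidean distances. Being unbiased, the estimate can be
#' slightly negative near the null; it is reported as-is.
#'
#' @param X1,X2 Numeric matrices (rows = samples) of equal column count.
#' @param sigma RBF bandwidth; `NULL` for the median heuristic.
#' @return The estimate (scalar). The bandwidth used is attached as
#'   `attr(x, "sigma")`.
#' @export
mmd2 <- function(X1, X2, sigma = NULL) {
  X1 <- as.matrix(X1)
  X2 <- as.matrix(X2)
  if (ncol(X1) != ncol(X2)) validationError("dimension mismatch between samples")
  n1 <- nrow(X1)
  n2 <- nrow(X2)
  stopifnot(n1 >= 2L, n2 >= 2L)
  X <- rbind(X1, X2)
  D2 <- squaredDistanceMatrix(X)
  if (is.null(sigma)) sigma <- medianHeuristicSigma(D2)
  K <- rbfFromD2(D2, sigma)
  i1 <- seq_len(n1)
  i2 <- n1 + seq_len(n2)
  K11 <- K[i1, i1]
  K22 <- K[i2, i2]
  K12 <- K[i1, i2]
  stat <- (sum(K11) - sum(diag(K11))) / (n1 * (n1 - 1)) +
    (sum(K22) - sum(diag(K22))) / (n2 * (n2 - 1)) -
    2 * sum(K12) / (n1 * n2)
  attr(stat, "sigma") <- sigma
  stat
}

#' Permutation test for the MMD two-sample statistic
#'
#' Tests H0: both samples come from the same distribution by recomputing the
#' unbiased squared MMD under random reassignments of the pooled sample
#' labels. The p-value uses the add-one rule
#' `p = (1 + #\{permuted >= observed\}) / (1 + nPerm)`, so `p >= 1/(1+nPerm)`
#' always. For quadratic-cost control the pooled kernel matrix is built once
#' and permutations are evaluated via indicator-vector quadratic forms; each
#' side can be subsampled to `subsampleCap` rows (seeded) beforehand.
#'
#' @inheritParams mmd2
#' @param nPerm Number of permutations.
#' @param seed Integer seed.
#' @param subsampleCap Maximum rows per side (default 2000).
#' @return List with `statistic`, `p.value`, `nPerm`, `sigma`, `n1`, `n2`.
#' @export
mmdPermutationTest <- function(X1, X2, nPerm = 1000L, seed = 0L, sigma = NULL,
                               subsampleCap = 2000L) {
  stopifnot(nPerm >= 1L)
  X1 <- as.matrix(X1)
  X2 <- as.matrix(X2)
  if (ncol(X1) != ncol(X2)) validationError("dimension mismatch between samples")
  set.seed(seed)
  if (nrow(X1) > subsampleCap) X1 <- X1[sample.int(nrow(X1), subsampleCap), , drop = FALSE]
  if (nrow(X2) > subsampleCap) X2 <- X2[sample.int(nrow(X2), subsampleCap), , drop = FALSE]
  n1 <- nrow(X1)
  n2 <- nrow(X2)
  stopifnot(n1 >= 2L, n2 >= 2L)
  n <- n1 + n2
  X <- rbind(X1, X2)
  D2 <- squaredDistanceMatrix(X)
  if (is.null(sigma)) sigma <- medianHeuristicSigma(D2)
  K <- rbfFromD2(D2, sigma)
  dK <- diag(K)
  rs <- rowSums(K)
  sumK <- sum(rs)
  sumdK <- sum(dK)

  statFrom <- function(q11, d1, c1) {
    q22 <- sumK - 2 * c1 + q11
    d2 <- sumdK - d1
    q12 <- c1 - q11
    (q11 - d1) / (n1 * (n1 - 1)) + (q22 - d2) / (n2 * (n2 - 1)) -
      2 * q12 / (n1 * n2)
  }

  i1 <- seq_len(n1)
  e1 <- numeric(n)
  e1[i1] <- 1
  obs <- statFrom(drop(crossprod(e1, K %*% e1)), sum(dK[i1]), sum(rs[i1]))

  idx <- matrix(0L, nrow = n1, ncol = nPerm)
  for (b in seq_len(nPerm)) idx[, b] <- sample.int(n, n1)
  E <- matrix(0, n, nPerm)
  E[cbind(as.vector(idx), rep(seq_len(nPerm), each = n1))] <- 1
  KE <- K %*% E
  q11 <- colSums(E * KE)
  d1 <- colSums(matrix(dK[idx], nrow = n1))
  c1 <- colSums(matrix(rs[idx], nrow = n1))
  perm <- statFrom(q11, d1, c1)

  list(statistic = obs, p.value = (1 + sum(perm >= obs)) / (1 + nPerm),
       nPerm = nPerm, sigma = sigma, n1 = n1, n2 = n2)
}

#' Bonferroni adjustment
#'
#' `p_i -> min(1, m * p_i)` with `m = length(p)`.
#'
#' @param pvals Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bonferroniAdjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  p.adjust(pvals, method = "bonferroni")
}

newShiftRow <- function(setting, kind, comparison, group, distance, p, n1, n2) {
  data.frame(setting = setting, kind = kind, comparison = comparison,
             group = group, distance = distance, p.value = p,
             p.adjusted = NA_real_, n1 = n1, n2 = n2,
             stringsAsFactors = FALSE)
}

#' In-distribution shift report: prevalence and representation shifts
#'
#' For every unordered pair of demographic groups, quantifies the prevalence
#' shift P(Y|A) as the total variation distance between the group
#' outcome distributions (tested with the two-sample binomial proportion
#' test) and the representation shift P(X|A) as the unbiased squared MMD
#' between the groups' embeddings (tested by permutation). All p-values in
#' the report form one Bonferroni family.
#'
#' @param pred A [PredictionSet-class].
#' @param emb The aligned [EmbeddingSet-class].
#' @param attribute Attribute name.
#' @param split Evaluation split (default `"test"`).
#' @param nPerm Permutations for the MMD test.
#' @param seed Integer seed.
#' @param subsampleCap Per-side subsample cap for the MMD test.
#' @return Data frame of class `fairshift_shift_report`: one row per test
#'   with `distance`, `p.value`, `p.adjusted`.
#' @export
shiftReportID <- function(pred, emb, attribute, split = "test",
                          nPerm = 1000L, seed = 0L, subsampleCap = 2000L) {
  y <- predLabels(pred, split = split)
  g <- groupLabels(pred, attribute, split = split)
  ge <- groupLabels(emb, attribute, split = split)
  M <- embMatrix(emb, split = split)
  groups <- sort(unique(g))
  sizes <- table(factor(g, levels = groups))
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning(sprintf("excluding group(s) with n < 2: %s", paste(small, collapse = ", ")))
    groups <- setdiff(groups, small)
  }
  if (length(groups) < 2L) validationError("need at least two groups")
  rows <- list()
  k <- 0L
  for (i in seq_len(length(groups) - 1L)) {
    for (j in seq(i + 1L, length(groups))) {
      a1 <- groups[i]
      a2 <- groups[j]
      y1 <- y[g == a1]
      y2 <- y[g == a2]
      bt <- binomialProportionTest(sum(y1), length(y1), sum(y2), length(y2))
      rows[[k <- k + 1L]] <- newShiftRow("ID", "prevalence P(Y|A)",
                                         paste(a1, "vs", a2), NA_character_,
                                         tvDistanceBinary(bt$p1, bt$p2),
                                         bt$p.value, length(y1), length(y2))
      mt <- mmdPermutationTest(M[ge == a1, , drop = FALSE],
                               M[ge == a2, , drop = FALSE],
                               nPerm = nPerm, seed = deriveSeed(seed, k),
                               subsampleCap = subsampleCap)
      rows[[k <- k + 1L]] <- newShiftRow("ID", "representation P(X|A)",
                                         paste(a1, "vs", a2), NA_character_,
                                         mt$statistic, mt$p.value, mt$n1, mt$n2)
    }
  }
  out <- do.call(rbind, rows)
  out$p.adjusted <- bonferroniAdjust(out$p.value)
  class(out) <- c("fairshift_shift_report", class(out))
  out
}

#' Out-of-distribution shift report: label, prevalence, covariate and
#' representation shifts
#'
#' Compares a source (ID) environment against a target (OOD) environment
#' under the null that each distribution is unchanged: one label-shift test
#' P(Y) and one covariate-shift test P(X) on the pooled samples, plus
#' per-group prevalence P(Y|A=a) and representation P(X|A=a) tests. Groups
#' present in only one environment are skipped with a warning. All p-values
#' form one Bonferroni family.
#'
#' @param predSrc,predTar Source / target [PredictionSet-class].
#' @param embSrc,embTar Source / target [EmbeddingSet-class].
#' @inheritParams shiftReportID
#' @return Data frame of class `fairshift_shift_report`.
#' @export
shiftReportOOD <- function(predSrc, predTar, embSrc, embTar, attribute,
                           split = "test", nPerm = 1000L, seed = 0L,
                           subsampleCap = 2000L) {
  ys <- predLabels(predSrc, split = split)
  yt <- predLabels(predTar, split = split)
  gs <- groupLabels(predSrc, attribute, split = split)
  gt <- groupLabels(predTar, attribute, split = split)
  Ms <- embMatrix(embSrc, split = split)
  Mt <- embMatrix(embTar, split = split)
  ges <- groupLabels(embSrc, attribute, split = split)
  get <- groupLabels(embTar, attribute, split = split)

  rows <- list()
  k <- 0L
  bt <- binomialProportionTest(sum(ys), length(ys), sum(yt), length(yt))
  rows[[k <- k + 1L]] <- newShiftRow("OOD", "label P(Y)", "src vs tar",
                                     NA_character_,
                                     tvDistanceBinary(bt$p1, bt$p2),
                                     bt$p.value, length(ys), length(yt))
  mt <- mmdPermutationTest(Ms, Mt, nPerm = nPerm, seed = deriveSeed(seed, k),
                           subsampleCap = subsampleCap)
  rows[[k <- k + 1L]] <- newShiftRow("OOD", "covariate P(X)", "src vs tar",
                                     NA_character_, mt$statistic, mt$p.value,
                                     mt$n1, mt$n2)
  shared <- intersect(unique(gs), unique(gt))
  lost <- setdiff(union(unique(gs), unique(gt)), shared)
  if (length(lost)) {
    warning(sprintf("group(s) present in only one environment skipped: %s",
                    paste(lost, collapse = ", ")))
  }
  for (a in sort(shared)) {
    y1 <- ys[gs == a]
    y2 <- yt[gt == a]
    bt <- binomialProportionTest(sum(y1), length(y1), sum(y2), length(y2))
    rows[[k <- k + 1L]] <- newShiftRow("OOD", "prevalence P(Y|A=a)", "src vs tar",
                                       a, tvDistanceBinary(bt$p1, bt$p2),
                                       bt$p.value, length(y1), length(y2))
    mt <- mmdPermutationTest(Ms[ges == a, , drop = FALSE],
                             Mt[get == a, , drop = FALSE],
                             nPerm = nPerm, seed = deriveSeed(seed, k),
                             subsampleCap = subsampleCap)
    rows[[k <- k + 1L]] <- newShiftRow("OOD", "representation P(X|A=a)",
                                       "src vs tar", a, mt$statistic,
                                       mt$p.value, mt$n1, mt$n2)
  }
  out <- do.call(rbind, rows)
  out$p.adjusted <- bonferroniAdjust(out$p.value)
  class(out) <- c("fairshift_shift_report", class(out))
  out
}
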