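# Fixture builders and independent brute-force oracles used across the
# suite. The oracles deliberately use naive algorithms (double loops,
# exhaustive enumeration) so they stay independent of the package's
# implementations.

makePred <- function(scores, labels, groups, split = "test",
                     environment = "site_a", task = "disease",
                     taskPolarity = "disease_indicator", attribute = "sex") {
  d <- data.frame(
    sample_id = sprintf("%s_%s_%05d", environment, split, seq_along(scores)),
    score = scores, label = labels, split = split, environment = environment,
    task = task, stringsAsFactors = FALSE)
  d[[attribute]] <- groups
  predictionSet(d, attrNames = attribute, task = task,
                taskPolarity = taskPolarity)
}

randPred <- function(n, seed, environment = "site_a", split = "test") {
  set.seed(seed)
  makePred(runif(n), rbinom(n, 1, 0.4),
           sample(c("female", "male"), n, replace = TRUE),
           split = split, environment = environment)
}

# AUROC by exhaustive pair counting over all (positive, negative) pairs.
aurocPairOracle <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# F1-optimal threshold by direct sweep over every unique score.
f1SweepOracle <- function(scores, labels) {
  cand <- sort(unique(scores))
  f1 <- vapply(cand, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    fn <- sum(!pred & labels == 1)
    if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  cand[which.max(f1)]
}

# ECE by direct per-bin accounting.
eceBinOracle <- function(scores, labels, nBins) {
  n <- length(scores)
  tot <- 0
  for (b in seq_len(nBins)) {
    lo <- (b - 1) / nBins
    hi <- b / nBins
    inBin <- if (b < nBins) scores >= lo & scores < hi else scores >= lo & scores <= hi
    if (any(inBin)) {
      tot <- tot + sum(inBin) / n * abs(mean(scores[inBin]) - mean(labels[inBin]))
    }
  }
  tot
}

# Pareto front by O(n^2) double-loop dominance.
paretoDominanceOracle <- function(perf, fair) {
  n <- length(perf)
  on <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (j != i && perf[j] >= perf[i] && fair[j] <= fair[i] &&
          (perf[j] > perf[i] || fair[j] < fair[i])) {
        dominated <- TRUE
        break
      }
    }
    on[i] <- !dominated
  }
  on
}

# Unbiased squared MMD by naive double-loop kernel sums.
mmd2LoopOracle <- function(X1, X2, sigma) {
  k <- function(a, b) exp(-sum((a - b)^2) / (2 * sigma^2))
  n1 <- nrow(X1)
  n2 <- nrow(X2)
  s11 <- 0
  for (i in seq_len(n1)) for (j in seq_len(n1)) {
    if (i != j) s11 <- s11 + k(X1[i, ], X1[j, ])
  }
  s22 <- 0
  for (i in seq_len(n2)) for (j in seq_len(n2)) {
    if (i != j) s22 <- s22 + k(X2[i, ], X2[j, ])
  }
  s12 <- 0
  for (i in seq_len(n1)) for (j in seq_len(n2)) s12 <- s12 + k(X1[i, ], X2[j, ])
  s11 / (n1 * (n1 - 1)) + s22 / (n2 * (n2 - 1)) - 2 * s12 / (n1 * n2)
}

# One-tailed ("a stochastically smaller") rank-sum p-value by exhaustive
# enumeration of all C(m+n, m) rank assignments; tie-free samples only.
wilcoxonEnumOracle <- function(a, b) {
  m <- length(a)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  obs <- sum(r[seq_len(m)])
  combos <- utils::combn(length(pooled), m)
  sums <- colSums(matrix(r[combos], nrow = m))
  mean(sums <= obs)
}
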