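#' @include AllGenerics.R
NULL

#' Define a synthetic audit scenario
#'
#' The synthetic cohort generator emulates the statistical structure of a
#' multi-site clinical imaging study with known ground truth: a binary (or
#' multi-level) demographic attribute A, a group-conditional disease
#' prevalence P(Y = 1 | A = a) per environment (the prevalence-shift
#' lever), and Gaussian representation vectors
#' `z = Y * betaY * u + kappa_e * c_a * v + eps`, `eps ~ N(0, sigma^2 I_d)`,
#' where `u` (disease axis) and `v` (attribute axis) are orthonormal and
#' `kappa_e` scales how strongly group identity is written into the
#' representation in environment `e` (the representation-shift lever).
#' `c_a` is the group's signed position on the attribute axis (+1/-1 for
#' binary groups).
#'
#' @param environments Named list; each element a list with `pi` (group
#'   proportions), `rho` (per-group prevalence) and `kappa` (attribute
#'   separation). Names are environment ids.
#' @param groups Group labels (default `c("female", "male")`).
#' @param attribute Attribute name (default `"sex"`).
#' @param d Embedding dimension (default 16).
#' @param betaY Disease signal strength (default 1.5).
#' @param sigma Isotropic noise SD (default 1).
#' @param task,taskPolarity Task name and polarity for generated
#'   [PredictionSet-class]s.
#' @param idEnvironment Designated ID environment (default: first).
#' @return A list of class `fairshiftScenario`.
#' @export
syntheticScenario <- function(environments, groups = c("female", "male"),
                              attribute = "sex", d = 16L, betaY = 1.5,
                              sigma = 1, task = "disease",
                              taskPolarity = "disease_indicator",
                              idEnvironment = names(environments)[1L]) {
  stopifnot(length(environments) >= 1L, !is.null(names(environments)),
            sigma > 0, d >= 2L, length(groups) >= 2L)
  for (nm in names(environments)) {
    e <- environments[[nm]]
    if (abs(sum(e$pi) - 1) > 1e-8) {
      validationError(sprintf("environment '%s': group proportions must sum to 1", nm))
    }
    if (length(e$pi) != length(groups) || length(e$rho) != length(groups)) {
      validationError(sprintf("environment '%s': pi and rho must have one entry per group", nm))
    }
    if (any(e$rho < 0 | e$rho > 1)) {
      validationError(sprintf("environment '%s': prevalences must lie in [0, 1]", nm))
    }
  }
  nG <- length(groups)
  attrSigns <- if (nG == 2L) c(1, -1) else seq(1, -1, length.out = nG)
  names(attrSigns) <- groups
  structure(list(environments = environments, groups = groups,
                 attribute = attribute, attrSigns = attrSigns,
                 d = as.integer(d), betaY = betaY, sigma = sigma,
                 task = task, taskPolarity = taskPolarity,
                 idEnvironment = idEnvironment),
            class = "fairshiftScenario")
}

#' @export
print.fairshiftScenario <- function(x, ...) {
  cat(sprintf("Synthetic scenario: %d environment(s), groups %s, d = %d\n",
              length(x$environments), paste(x$groups, collapse = "/"), x$d))
  for (nm in names(x$environments)) {
    e <- x$environments[[nm]]
    cat(sprintf("  %s%s: pi = (%s), rho = (%s), kappa = %g\n", nm,
                if (nm == x$idEnvironment) " [ID]" else "",
                paste(e$pi, collapse = ", "), paste(e$rho, collapse = ", "),
                e$kappa))
  }
  invisible(x)
}

#' Sample one environment of a synthetic scenario
#'
#' Draws `A ~ Categorical(pi_e)`, `Y | A = a ~ Bernoulli(rho_{e,a})` and
#' the representation vectors `z`; deterministic under the seed.
#'
#' @param scenario A `fairshiftScenario`.
#' @param environment Environment id.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return List with `A` (group labels), `Y` (0/1), `Z` (n x d matrix),
#'   `linU` and `linV` (the disease-axis and attribute-axis coordinates of
#'   `Z`).
#' @export
sampleEnvironment <- function(scenario, environment, n, seed = 0L) {
  env <- scenario$environments[[environment]]
  if (is.null(env)) validationError(sprintf("unknown environment '%s'", environment))
  stopifnot(n >= 1L)
  set.seed(seed)
  A <- sample(scenario$groups, n, replace = TRUE, prob = env$pi)
  rho <- setNames(env$rho, scenario$groups)
  Y <- rbinom(n, 1L, rho[A])
  Z <- matrix(rnorm(n * scenario$d, sd = scenario$sigma), nrow = n)
  cA <- scenario$attrSigns[A]
  # u = e1 (disease axis), v = e2 (attribute axis): orthonormal by
  # construction
  Z[, 1L] <- Z[, 1L] + Y * scenario$betaY
  Z[, 2L] <- Z[, 2L] + env$kappa * cA
  list(A = unname(A), Y = Y, Z = Z, linU = Z[, 1L], linV = Z[, 2L])
}

#' Define a synthetic model
#'
#' A synthetic model scores a representation `z` through a unit direction
#' `w = cos(theta) u + sin(theta) v`: `score = logistic(gamma (w.z + b))`.
#' `theta` is the shortcut-reliance angle (0 = pure disease signal, pi/2 =
#' pure demographic shortcut). The model's emitted 2-D embedding is
#' `[w.z, eta (v.z)] + N(0, embNoise^2)`, so `eta` controls how much
#' attribute information the representation retains. `noiseSd` adds
#' model-specific score noise ("skill" variation) on the linear scale; the
#' closed-form group rates account for it.
#'
#' @param theta Shortcut angle in `[0, pi/2]`.
#' @param eta Representation-leak strength, `>= 0`.
#' @param gamma Score scale.
#' @param b Intercept on the linear scale.
#' @param noiseSd Model-specific score noise SD (default 0).
#' @param embNoise Embedding noise SD (default 0.1).
#' @param algorithm Algorithm tag.
#' @param modelId Model id.
#' @return A list of class `fairshiftModel`.
#' @export
syntheticModel <- function(theta, eta = 0, gamma = 2.5, b = 0, noiseSd = 0,
                           embNoise = 0.1, algorithm = "erm-like",
                           modelId = "m01") {
  stopifnot(theta >= 0, theta <= pi / 2 + 1e-12, eta >= 0, noiseSd >= 0)
  structure(list(theta = theta, eta = eta, gamma = gamma, b = b,
                 noiseSd = noiseSd, embNoise = embNoise,
                 algorithm = algorithm, modelId = modelId),
            class = "fairshiftModel")
}

#' Score samples with a synthetic model
#'
#' @param model A `fairshiftModel`.
#' @param samples Output of [sampleEnvironment()] (or a matrix `Z`).
#' @param seed Seed for the model's score noise (required when
#'   `noiseSd > 0`).
#' @return List with `score` (probabilities in (0, 1)) and `linear` (the
#'   noisy linear score `w.z`).
#' @export
scoreModel <- function(model, samples, seed = 0L) {
  Z <- if (is.matrix(samples)) samples else samples$Z
  lin <- Z[, 1L] * cos(model$theta) + Z[, 2L] * sin(model$theta)
  if (model$noiseSd > 0) {
    set.seed(seed)
    lin <- lin + rnorm(length(lin), sd = model$noiseSd)
  }
  list(score = plogis(model$gamma * (lin + model$b)), linear = lin)
}

#' Closed-form per-group error rates of a synthetic model
#'
#' For binary groups the linear score is Gaussian given (Y, A):
#' `w.z | (Y, A = a) ~ N(Y betaY cos(theta) + kappa_e c_a sin(theta), s^2)`
#' with `s^2 = sigma^2 + noiseSd^2`, so at a threshold `t` on the linear
#' score:
#' `FPR_a = Phi((kappa_e c_a sin(theta) - t)/s)` and
#' `FNR_a = Phi((t - betaY cos(theta) - kappa_e c_a sin(theta))/s)`.
#' These are the binding oracle for the empirical fairness metrics on
#' synthetic data.
#'
#' @param scenario A `fairshiftScenario`.
#' @param environment Environment id.
#' @param model A `fairshiftModel`.
#' @param threshold Threshold `t` on the linear score `w.z`.
#' @return Data frame with one row per group: `group`, `fpr`, `fnr`.
#' @export
analyticGroupRates <- function(scenario, environment, model, threshold) {
  env <- scenario$environments[[environment]]
  if (is.null(env)) validationError(sprintf("unknown environment '%s'", environment))
  if (scenario$sigma <= 0) validationError("sigma must be positive")
  s <- sqrt(scenario$sigma^2 + model$noiseSd^2)
  mu <- env$kappa * scenario$attrSigns * sin(model$theta)
  data.frame(
    group = scenario$groups,
    fpr = pnorm((mu - threshold) / s),
    fnr = pnorm((threshold - scenario$betaY * cos(model$theta) - mu) / s),
    row.names = NULL, stringsAsFactors = FALSE)
}

zooSamplesToPredictionSet <- function(scenario, model, env, splits, seed) {
  rows <- list()
  embRows <- list()
  embMat <- list()
  for (i in seq_along(splits)) {
    split <- names(splits)[i]
    smp <- splits[[i]]
    n <- length(smp$Y)
    sc <- scoreModel(model, smp, seed = deriveSeed(seed, 7L * i + 1L))
    d <- data.frame(
      sample_id = sprintf("%s_%s_%05d", env, split, seq_len(n)),
      score = sc$score, label = smp$Y, split = split, environment = env,
      task = scenario$task, stringsAsFactors = FALSE)
    d[[scenario$attribute]] <- smp$A
    rows[[i]] <- d
    # embedding: clean model direction plus eta-scaled attribute axis
    linW <- smp$Z[, 1L] * cos(model$theta) + smp$Z[, 2L] * sin(model$theta)
    set.seed(deriveSeed(seed, 7L * i + 2L))
    E <- cbind(linW, model$eta * smp$linV) +
      matrix(rnorm(2L * n, sd = model$embNoise), ncol = 2L)
    embMat[[i]] <- E
    embRows[[i]] <- d[c("sample_id", "split", "environment", scenario$attribute)]
  }
  pred <- predictionSet(do.call(rbind, rows), attrNames = scenario$attribute,
                        task = scenario$task,
                        taskPolarity = scenario$taskPolarity)
  emb <- embeddingSet(do.call(rbind, embMat), do.call(rbind, embRows),
                      attrNames = scenario$attribute)
  list(pred = pred, emb = emb)
}

#' Generate a synthetic model zoo as a ModelGrid
#'
#' Samples each environment once per split (all models score the same
#' cohort, as in a real benchmark) and builds a full [ModelGrid-class]
#' with per-model [PredictionSet-class]s and 2-D [EmbeddingSet-class]s.
#'
#' @param scenario A `fairshiftScenario`.
#' @param models List of `fairshiftModel` (e.g. from [syntheticModel()]),
#'   or a data frame with columns `theta`, `eta`, `gamma`, `b`, `noiseSd`,
#'   `embNoise`, `algorithm`, `modelId`.
#' @param nTrain,nVal,nTest Samples per split in every environment.
#' @param seed Master seed; everything else derives from it.
#' @return A [ModelGrid-class].
#' @export
makeModelZoo <- function(scenario, models, nTrain = 1000L, nVal = 500L,
                         nTest = 1000L, seed = 0L) {
  if (is.data.frame(models)) {
    models <- lapply(seq_len(nrow(models)), function(i) {
      do.call(syntheticModel, as.list(models[i, , drop = FALSE]))
    })
  }
  stopifnot(length(models) >= 2L)
  envNames <- names(scenario$environments)
  nSplit <- c(train = nTrain, val = nVal, test = nTest)
  cohorts <- list()
  for (ie in seq_along(envNames)) {
    splits <- list()
    for (is in seq_along(nSplit)) {
      splits[[names(nSplit)[is]]] <- sampleEnvironment(
        scenario, envNames[ie], nSplit[is],
        seed = deriveSeed(seed, 97L * ie + is))
    }
    cohorts[[envNames[ie]]] <- splits
  }
  entries <- lapply(seq_along(models), function(k) {
    m <- models[[k]]
    preds <- list()
    embs <- list()
    for (ie in seq_along(envNames)) {
      env <- envNames[ie]
      out <- zooSamplesToPredictionSet(scenario, m, env, cohorts[[env]],
                                       seed = deriveSeed(seed, 1000L * k + 13L * ie))
      preds[[env]] <- out$pred
      embs[[env]] <- out$emb
    }
    modelEntry(m$modelId, predictions = preds, embeddings = embs,
               algorithm = m$algorithm,
               hparamTag = sprintf("theta%.3f_eta%.3f_noise%.2f",
                                   m$theta, m$eta, m$noiseSd),
               seed = k)
  })
  assembleGrid(entries, scenario$idEnvironment)
}

defaultZooModels <- function(betaY = 1.5) {
  thetas <- seq(0, 0.9, length.out = 8L)
  k <- 0L
  models <- list()
  for (it in seq_along(thetas)) {
    for (r in 1:3) {
      k <- k + 1L
      th <- thetas[it]
      models[[k]] <- syntheticModel(
        theta = th,
        eta = max(0, 1.5 * sin(th) + 0.15 * (r - 2)),
        gamma = 2.5, b = -0.5 * betaY * cos(th),
        noiseSd = c(0, 0.35, 0.7)[r], embNoise = 1.0,
        algorithm = if (th < 0.45) "debiased-like" else "erm-like",
        modelId = sprintf("m%02d_t%03.0f_r%d", k, 100 * th, r))
    }
  }
  models
}

s3TargetEnvironments <- function() {
  kappas <- c(-1.5, -0.8, 0.5, 1.2)
  rhos <- list(c(0.15, 0.45), c(0.30, 0.30), c(0.45, 0.20))
  envs <- list()
  k <- 0L
  for (kp in kappas) {
    for (rh in rhos) {
      k <- k + 1L
      envs[[sprintf("site_b%02d", k)]] <-
        list(pi = c(0.5, 0.5), rho = rh, kappa = kp)
    }
  }
  envs
}

#' Canned audit scenarios S1, S2 and S3
#'
#' Three fully parameterized study designs over a shared 24-model zoo
#' (8 shortcut angles x 3 replicates with increasing score noise; the
#' representation leak grows with the angle, and low-angle models carry a
#' `"debiased-like"` tag, high-angle models `"erm-like"`):
#'
#' * **S1** (encoding vs unfairness): one environment with unequal
#'   group prevalences and a strong attribute axis; exercises the
#'   encoding-fairness correlation.
#' * **S2** (fairness non-transfer): S1 plus one target environment whose
#'   attribute axis is sign-flipped and whose group prevalences are
#'   reversed, so the shortcut keeps (some) aggregate predictive value but
#'   reverses which group it harms; exercises transfer correlations, front
#'   transfer and the gap decomposition.
#' * **S3** (selection): S1 plus 12 target environments spanning a grid of
#'   attribute-axis strengths and prevalence patterns, giving 12 settings
#'   for oracle-regret evaluation of the selection criteria.
#'
#' @param name `"S1"`, `"S2"` or `"S3"`.
#' @param seed Master seed for the generated grid. The default (1) is the
#'   shipped configuration: the scenarios are constructed counter-examples,
#'   and their qualitative properties are guaranteed at the shipped seed.
#' @param nTrain,nVal,nTest Per-split cohort sizes.
#' @return List with `name`, `scenario`, `models`, `grid`
#'   (a [ModelGrid-class]), `attribute`, `groupPair` and `settings` (a data
#'   frame; one row per OOD setting, `NULL`-rows for S1).
#' @export
cannedScenarios <- function(name = c("S1", "S2", "S3"), seed = 1L,
                            nTrain = 1000L, nVal = 500L, nTest = 1000L) {
  name <- match.arg(name)
  idEnv <- list(site_a = list(pi = c(0.5, 0.5), rho = c(0.50, 0.10), kappa = 2.0))
  envs <- switch(name,
    S1 = idEnv,
    S2 = c(idEnv, list(site_b = list(pi = c(0.5, 0.5), rho = c(0.15, 0.45),
                                     kappa = -1.2))),
    S3 = c(idEnv, s3TargetEnvironments()))
  scenario <- syntheticScenario(envs, groups = c("female", "male"),
                                attribute = "sex", idEnvironment = "site_a")
  models <- defaultZooModels(scenario$betaY)
  grid <- makeModelZoo(scenario, models, nTrain = nTrain, nVal = nVal,
                       nTest = nTest, seed = seed)
  oodEnvs <- setdiff(names(envs), "site_a")
  settings <- if (length(oodEnvs)) {
    data.frame(tarEnv = oodEnvs, attribute = "sex",
               group1 = "female", group2 = "male", stringsAsFactors = FALSE)
  } else NULL
  list(name = name, scenario = scenario, models = models, grid = grid,
       attribute = "sex", groupPair = c("female", "male"),
       settings = settings)
}
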