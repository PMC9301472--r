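#' Synthetic cohort configuration
#'
#' Defines the statistical structure of a simulated multi-site cohort: a
#' sparse set of planted edges linearly coupled to the severity score, plus
#' optional site offsets and age/sex effects on the score. Defaults are the
#' package's reference recovery conditions: 300 subjects, 30 ROIs, 15
#' planted edges, and a planted signal-to-total variance fraction of 0.64
#' (theoretical ceiling r = 0.8 between score and signal), with covariate
#' effects switched off so the signal fraction is exact.
#'
#' @slot nSubjects,nROIs,nTimepoints Cohort dimensions.
#' @slot nSites Number of acquisition sites.
#' @slot siteOffset Additive score offset per site index step.
#' @slot supportSize Number of planted upper-triangle edges.
#' @slot beta Planted weight scale.
#' @slot noiseSd Score noise standard deviation; `NA` derives it from
#'   `signalFrac`.
#' @slot signalFrac Target planted-signal fraction of total score variance.
#' @slot nBlocks,rhoWithin,rhoBetween Community structure of the
#'   time-series covariance (time-series mode).
#' @slot ageEffect,sexEffect Linear covariate effects on the score.
#' @slot targetMean Score intercept.
#' @slot mode `"direct"` (symmetric matrices drawn directly) or
#'   `"timeseries"` (scores computed after the Pearson pipeline).
#' @slot sparsity Thresholding sparsity assumed when planting the signal.
#' @slot seed Integer seed; all generators are bitwise-reproducible given
#'   the config.
#' @export
setClass("SimulationConfig",
  slots = c(
    nSubjects = "integer", nROIs = "integer", nTimepoints = "integer",
    nSites = "integer", siteOffset = "numeric", supportSize = "integer",
    beta = "numeric", noiseSd = "numeric", signalFrac = "numeric",
    nBlocks = "integer", rhoWithin = "numeric", rhoBetween = "numeric",
    ageEffect = "numeric", sexEffect = "numeric", targetMean = "numeric",
    mode = "character", sparsity = "numeric", seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  n <- object@nROIs
  if (object@supportSize > n * (n - 1) / 2)
    return("supportSize exceeds the number of undirected edges")
  if (!object@mode %in% c("direct", "timeseries"))
    return("mode must be 'direct' or 'timeseries'")
  if (!is.na(object@noiseSd) && object@noiseSd < 0)
    return("noiseSd must be >= 0")
  if (!is.na(object@signalFrac) &&
    (object@signalFrac <= 0 || object@signalFrac >= 1))
    return("signalFrac must be in (0, 1)")
  TRUE
})

#' Construct a SimulationConfig
#'
#' @param nSubjects,nROIs,nTimepoints,nSites,siteOffset,supportSize,beta
#'   See [SimulationConfig-class].
#' @param noiseSd,signalFrac,nBlocks,rhoWithin,rhoBetween See
#'   [SimulationConfig-class].
#' @param ageEffect,sexEffect,targetMean,mode,sparsity,seed See
#'   [SimulationConfig-class].
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(nSubjects = 300L, nROIs = 30L,
                             nTimepoints = 150L, nSites = 4L,
                             siteOffset = 0, supportSize = 15L, beta = 0.5,
                             noiseSd = NA_real_, signalFrac = 0.64,
                             nBlocks = 3L, rhoWithin = 0.35,
                             rhoBetween = 0.05, ageEffect = 0, sexEffect = 0,
                             targetMean = 6, mode = c("direct", "timeseries"),
                             sparsity = 0.05, seed = 1L) {
  mode <- match.arg(mode)
  new("SimulationConfig",
    nSubjects = as.integer(nSubjects), nROIs = as.integer(nROIs),
    nTimepoints = as.integer(nTimepoints), nSites = as.integer(nSites),
    siteOffset = siteOffset, supportSize = as.integer(supportSize),
    beta = beta, noiseSd = noiseSd, signalFrac = signalFrac,
    nBlocks = as.integer(nBlocks), rhoWithin = rhoWithin,
    rhoBetween = rhoBetween, ageEffect = ageEffect, sexEffect = sexEffect,
    targetMean = targetMean, mode = mode, sparsity = sparsity,
    seed = as.integer(seed)
  )
}

#' Block-community covariance matrix
#'
#' Correlation matrix with `nBlocks` equal communities: `rhoWithin` inside a
#' block, `rhoBetween` across blocks, unit diagonal. Jittered toward the
#' identity if not positive definite.
#'
#' @param n Number of ROIs.
#' @param nBlocks Number of communities.
#' @param rhoWithin,rhoBetween Within/between-block correlations.
#' @return Positive-definite `n x n` covariance matrix.
#' @export
blockCovariance <- function(n, nBlocks = 3L, rhoWithin = 0.35,
                            rhoBetween = 0.05) {
  block <- rep_len(seq_len(nBlocks), n)
  block <- sort(block)
  S <- matrix(rhoBetween, n, n)
  for (b in seq_len(nBlocks)) {
    idx <- which(block == b)
    S[idx, idx] <- rhoWithin
  }
  diag(S) <- 1
  for (jit in c(0, 1e-6, 1e-4, 1e-2)) {
    Sj <- (1 - jit) * S + jit * diag(n)
    if (min(eigen(Sj, symmetric = TRUE, only.values = TRUE)$values) > 1e-10)
      return(Sj)
  }
  stop("block covariance is not positive definite even after jitter",
    call. = FALSE)
}

#' Simulate one subject's ROI time series
#'
#' Draws `nTimepoints` samples from a zero-mean multivariate normal with
#' block-community covariance, optionally perturbed per subject.
#'
#' @param config A [SimulationConfig-class].
#' @param seed Seed for this subject's draw.
#' @param Sigma Optional covariance override (e.g. a subject-specific
#'   perturbation of [blockCovariance()]).
#' @return `nTimepoints x nROIs` matrix with ROI column names.
#' @export
simulateTimeseries <- function(config, seed = config@seed, Sigma = NULL) {
  n <- config@nROIs
  if (is.null(Sigma))
    Sigma <- blockCovariance(n, config@nBlocks, config@rhoWithin,
      config@rhoBetween)
  Rchol <- chol(Sigma)
  withSeed(seed, {
    Z <- matrix(rnorm(config@nTimepoints * n), config@nTimepoints, n)
    ts <- Z %*% Rchol
    colnames(ts) <- paste0("ROI", seq_len(n))
    ts
  })
}

## draw one raw symmetric matrix: N(0,1) null edges, inflated +-(4 + |N(0,.5)|)
## values on the planted support so support edges survive thresholding
drawDirectMatrix <- function(n, supportPairs) {
  pairs <- upperTriPairs(n)
  vals <- rnorm(nrow(pairs))
  if (nrow(supportPairs)) {
    sidx <- match(
      paste(supportPairs[, 1], supportPairs[, 2]),
      paste(pairs[, 1], pairs[, 2])
    )
    signs <- sample(c(-1, 1), nrow(supportPairs), replace = TRUE)
    vals[sidx] <- signs * (4 + abs(rnorm(nrow(supportPairs), sd = 0.5)))
  }
  symFromUpper(vals, n)
}

#' Simulate a multi-site cohort with a planted edge signal
#'
#' Generates `nSubjects` connectivity matrices (directly, or through the
#' time-series + Pearson pipeline), plants `supportSize` upper-triangle
#' edges whose *preprocessed* (thresholded + standardized) values are
#' linearly coupled to the severity score:
#' `y = targetMean + sum_support W*_ij g_ij + site + age + sex + noise`.
#' Planted edge magnitudes are inflated so they survive proportional
#' thresholding with high probability. When `noiseSd` is `NA`, the noise is
#' scaled so the planted signal accounts for exactly `signalFrac` of the
#' empirical score variance (given zero covariate effects). Ages are drawn
#' uniform on \[7, 30\] and sex Bernoulli(0.5), echoing a developmental
#' cohort's demographic range.
#'
#' @param config A [SimulationConfig-class].
#' @return List with `cohort` (raw [ConnectivityCohort-class], target
#'   `"score"`) and `truth` (planted weight matrix `Wstar`, `support` pairs,
#'   per-subject `signal`, `sigma`, covariate effect sizes). The truth is
#'   also stored in the cohort metadata as `groundTruth`.
#' @export
simulateCohort <- function(config) {
  n <- config@nROIs
  N <- config@nSubjects
  withSeed(config@seed, {
    pairs <- upperTriPairs(n)
    support <- pairs[sort(sample.int(nrow(pairs), config@supportSize)), ,
      drop = FALSE]
    wvals <- config@beta * sample(c(-1, 1), nrow(support), replace = TRUE) *
      runif(nrow(support), 0.8, 1.2)
    Wstar <- matrix(0, n, n)
    Wstar[support] <- wvals
    Wstar[support[, c(2, 1)]] <- wvals

    site <- sample.int(config@nSites, N, replace = TRUE)
    age <- runif(N, 7, 30)
    sex <- rbinom(N, 1, 0.5)

    if (config@mode == "direct") {
      mats <- lapply(seq_len(N), function(k) drawDirectMatrix(n, support))
      kind <- "raw"
    } else {
      Sigma <- blockCovariance(n, config@nBlocks, config@rhoWithin,
        config@rhoBetween)
      seeds <- sample.int(.Machine$integer.max %/% 2L, N)
      mats <- lapply(seq_len(N), function(k) {
        ts <- simulateTimeseries(config, seed = seeds[k], Sigma = Sigma)
        base <- pearsonConnectivity(ts)@values
        ## plant inflated support edges on top of the correlation structure
        sv <- sample(c(-1, 1), nrow(support), replace = TRUE) *
          (4 + abs(rnorm(nrow(support), sd = 0.5)))
        base[support] <- sv
        base[support[, c(2, 1)]] <- sv
        diag(base) <- 1
        base
      })
      kind <- "raw"
    }

    ## the score couples to the *model input*: the thresholded+standardized
    ## edge values the preprocessing pipeline will reproduce exactly
    signal <- vapply(mats, function(m) {
      mt <- thresholdCore(m, config@sparsity)
      ms <- standardizeCore(mt)
      sum(Wstar[support] * ms[support])
    }, numeric(1))

    sigma <- config@noiseSd
    if (is.na(sigma)) {
      vs <- mean((signal - mean(signal))^2)
      sigma <- sqrt(vs * (1 - config@signalFrac) / config@signalFrac)
    }
    y <- config@targetMean + signal +
      config@siteOffset * (site - 1) +
      config@ageEffect * (age - mean(age)) +
      config@sexEffect * sex +
      rnorm(N, 0, sigma)

    ph <- data.frame(
      subject_id = sprintf("sub%04d", seq_len(N)),
      site = paste0("site", site), age = age, sex = sex, score = y
    )
    cms <- lapply(seq_len(N), function(k) {
      ConnectivityMatrix(mats[[k]], subjectId = ph$subject_id[k], kind = kind)
    })
    cohort <- ConnectivityCohort(cms, ph, targetName = "score")
    truth <- list(
      Wstar = Wstar, support = support, signal = signal, sigma = sigma,
      siteOffset = config@siteOffset, ageEffect = config@ageEffect,
      sexEffect = config@sexEffect, config = config
    )
    md <- S4Vectors::metadata(cohort)
    md$groundTruth <- truth
    S4Vectors::metadata(cohort) <- md
    list(cohort = cohort, truth = truth)
  })
}

#' Five-node toy graph
#'
#' The fixed documentation fixture: five nodes with the five undirected,
#' unweighted edges 1-2, 1-3, 2-3, 3-4, 4-5 (node degrees 2, 2, 3, 2, 1),
#' handy for walking through the extractor and pooling layers by hand.
#'
#' @return A [ConnectivityMatrix-class] flagged as thresholded.
#' @export
toyGraphFixture <- function() {
  n <- 5L
  m <- matrix(0, n, n)
  edges <- rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4), c(4, 5))
  m[edges] <- 1
  m[edges[, c(2, 1)]] <- 1
  ConnectivityMatrix(m, roiLabels = paste0("node", 1:5), subjectId = "toy",
    kind = "raw", isThresholded = TRUE)
}

#' Signal-recovery experiment on a synthetic cohort
#'
#' The package's end-to-end validation: simulate a seeded cohort under the
#' reference recovery conditions, preprocess it, run nested cross-validated
#' training, and measure (i) pooled held-out prediction accuracy against
#' the predict-the-mean baseline and (ii) how sharply group saliency
#' concentrates on the planted edges (precision among the top
#' `supportSize` edges versus the chance rate `s / (n(n-1)/2)`).
#'
#' @param seed Integer seed driving simulation, initialization, folds and
#'   batches.
#' @param epochs Training epochs per fold.
#' @param nMaps Feature maps per extractor layer.
#' @param lr0 Initial learning rate.
#' @param simConfig Optional [SimulationConfig-class] override.
#' @param tconfig Optional [TrainConfig-class] override (its seed/epochs are
#'   replaced by the arguments above).
#' @param adjacencyMode Adjacency embedding variant.
#' @return List with `metrics` (pooled mae, r, p), `baselineMAE`,
#'   `saliencyPrecision`, `chancePrecision`, `predictions`, `cv`, `truth`.
#' @export
recoveryExperiment <- function(seed = 1L, epochs = 200L, nMaps = 8L,
                               lr0 = 0.001, simConfig = NULL, tconfig = NULL,
                               adjacencyMode = "identity") {
  if (is.null(simConfig)) simConfig <- simulationConfig(seed = seed)
  sim <- simulateCohort(simConfig)
  built <- buildCohort(sim$cohort, sparsity = simConfig@sparsity)
  mconfig <- modelConfig(
    nROIs = simConfig@nROIs, nMaps = nMaps,
    adjacencyMode = adjacencyMode
  )
  if (is.null(tconfig)) tconfig <- trainConfig(lr0 = lr0, clipNorm = 25)
  tconfig@epochs <- as.integer(epochs)
  tconfig@seed <- as.integer(seed)
  cv <- crossValidate(built, mconfig, tconfig, keepModels = TRUE)

  y <- severityTarget(built)
  baselineMAE <- mean(abs(y - mean(y)))

  ## per-subject saliency from the fold model that held the subject out
  gs <- connMatrices(built)
  fold <- cv$predictions$fold
  maps <- lapply(seq_along(gs), function(k) {
    saliencyMap(gs[[k]], cv$models[[fold[k]]])
  })
  grp <- groupSaliency(maps, keepFraction = 0.1, roiLabels = roiLabels(built))
  n <- simConfig@nROIs
  pairs <- upperTriPairs(n)
  vals <- abs(grp$map[pairs])
  s <- simConfig@supportSize
  top <- order(-vals)[seq_len(s)]
  inSupport <- paste(pairs[, 1], pairs[, 2]) %in%
    paste(sim$truth$support[, 1], sim$truth$support[, 2])
  precision <- mean(inSupport[top])

  list(
    metrics = cv$metrics, baselineMAE = baselineMAE,
    saliencyPrecision = precision,
    chancePrecision = s / nrow(pairs),
    predictions = cv$predictions, cv = cv, truth = sim$truth,
    groupSaliency = grp
  )
}
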