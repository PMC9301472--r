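#' Cosine learning-rate schedule
#'
#' Anneals the learning rate from `lr0` at epoch 0 to exactly 0 at epoch
#' `T`: `alpha_t = 0.5 * (1 + cos(t * pi / T)) * lr0`.
#'
#' @param t Current epoch (0-based), `0 <= t <= T`.
#' @param T Total number of epochs.
#' @param lr0 Initial learning rate.
#' @return Learning rate at epoch `t`.
#' @export
#' @examples
#' cosineLR(0, 1000, 1e-5) # 1e-5
#' cosineLR(500, 1000, 1e-5) # 5e-6
cosineLR <- function(t, T, lr0) {
  if (any(t < 0) || any(t > T))
    stop("epoch t must satisfy 0 <= t <= T", call. = FALSE)
  0.5 * (1 + cos(t * pi / T)) * lr0
}

#' Deterministic fold assignment
#'
#' Shuffles subjects with the given seed and deals them round-robin into
#' `k` folds, so every subject appears in exactly one test fold.
#'
#' @param ids Subject identifiers (or an integer count).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold labels (1..k), one per subject.
#' @export
makeFolds <- function(ids, k = 5L, seed = 1L) {
  N <- if (length(ids) == 1 && is.numeric(ids)) as.integer(ids) else length(ids)
  if (N < k) stop("fewer subjects (", N, ") than folds (", k, ")",
    call. = FALSE)
  withSeed(seed, {
    fold <- integer(N)
    fold[sample.int(N)] <- rep_len(seq_len(k), N)
    fold
  })
}

## plain-list view of a ModelConfig for the compiled core
cfgList <- function(config) {
  list(
    n = config@nROIs, d = config@nMaps, nE2E = config@nE2ELayers,
    LAtt = config@nAttLayers, pAtt = config@pAtt, ratio = config@poolRatio,
    slope = config@leakySlope,
    mode = match(config@adjacencyMode, c("identity", "e2e", "averaging")) - 1L
  )
}

## mean-squared-error loss and summed parameter gradients over a batch
## (compiled core; mirrored by the reference R path, see modelBackward)
batchPass <- function(gs, y, params, config, adjGrad) {
  cppBatchGrad(gs, y, params, cfgList(config), adjGrad == "straight")
}

predictScores <- function(gs, params, config) {
  as.vector(cppPredictMany(gs, params, cfgList(config)))
}

#' Train the model on one split
#'
#' Stochastic gradient descent with momentum and weight decay on the
#' mean-squared-error loss, with a cosine learning-rate schedule per epoch
#' and seeded shuffled mini-batches. Weight decay is implemented by adding
#' `weightDecay * theta` to the gradient (equivalent to the gradient of an
#' added penalty `(weightDecay/2) * ||theta||^2`). After every epoch the
#' inner-validation mean absolute error is evaluated and the parameters of
#' the best-validation epoch are returned (early-stopping-style model
#' selection).
#'
#' @param cohort A preprocessed [ConnectivityCohort-class].
#' @param trainIdx,valIdx Subject indices for training and inner validation.
#' @param mconfig A [ModelConfig-class].
#' @param tconfig A [TrainConfig-class] (its `seed` controls initialization
#'   and batch shuffling).
#' @param adjGrad Gradient rule for the hard adjacency threshold:
#'   `"straight"` (straight-through, default) or `"detach"`.
#' @param targetName Optional override of the cohort's target column.
#' @return A [SeverityModel-class] holding the best-validation parameters
#'   and the per-epoch history (`epoch`, `lr`, `trainLoss`, `valMAE`).
#' @export
trainModel <- function(cohort, trainIdx, valIdx, mconfig, tconfig,
                       adjGrad = c("straight", "detach"), targetName = NULL) {
  adjGrad <- match.arg(adjGrad)
  gs <- connMatrices(cohort)
  y <- severityTarget(cohort, targetName)
  gsTr <- gs[trainIdx]
  yTr <- y[trainIdx]
  gsVal <- gs[valIdx]
  yVal <- y[valIdx]
  Tep <- tconfig@epochs

  params <- initParams(mconfig, tconfig@seed)
  vel <- zeroLike(params)
  best <- list(mae = Inf, params = params, epoch = 0L)
  hist <- data.frame(
    epoch = seq_len(Tep), lr = NA_real_, trainLoss = NA_real_,
    valMAE = NA_real_
  )

  withSeed(tconfig@seed + 1L, {
    nTr <- length(gsTr)
    for (ep in seq_len(Tep)) {
      lr <- cosineLR(ep - 1L, Tep, tconfig@lr0)
      ord <- sample.int(nTr)
      epLoss <- 0
      nb <- 0L
      for (start in seq(1L, nTr, by = tconfig@batchSize)) {
        sel <- ord[start:min(start + tconfig@batchSize - 1L, nTr)]
        bp <- batchPass(gsTr[sel], yTr[sel], params, mconfig, adjGrad)
        if (!is.finite(bp$loss))
          stop("training diverged (non-finite loss) at epoch ", ep,
            call. = FALSE)
        if (is.finite(tconfig@clipNorm)) {
          gn <- sqrt(sum(paramsToVector(bp$grads)^2))
          if (gn > tconfig@clipNorm)
            bp$grads <- mapParams1(bp$grads,
              function(x) x * (tconfig@clipNorm / gn))
        }
        ## v <- mu v - lr (grad + wd * theta); theta <- theta + v
        vel <- mapParams(
          vel, mapParams(bp$grads, params,
            function(g, p) g + tconfig@weightDecay * p),
          function(v, g) tconfig@momentum * v - lr * g
        )
        params <- mapParams(params, vel, `+`)
        epLoss <- epLoss + bp$loss
        nb <- nb + 1L
      }
      valMAE <- if (length(valIdx)) {
        mean(abs(predictScores(gsVal, params, mconfig) - yVal))
      } else NA_real_
      hist$lr[ep] <- lr
      hist$trainLoss[ep] <- epLoss / nb
      hist$valMAE[ep] <- valMAE
      if (length(valIdx) && valMAE < best$mae) {
        best <- list(mae = valMAE, params = params, epoch = ep)
      }
    }
  })
  if (!length(valIdx)) best <- list(mae = NA_real_, params = params, epoch = Tep)
  new("SeverityModel",
    config = mconfig, params = best$params, history = hist,
    bestEpoch = as.integer(best$epoch)
  )
}

#' @describeIn trainModel Compact display of a trained model.
#' @param object A SeverityModel.
#' @export
setMethod("show", "SeverityModel", function(object) {
  cat(sprintf(
    "SeverityModel: n=%d, d=%d, adjacency=%s; %d epochs trained, best epoch %d\n",
    object@config@nROIs, object@config@nMaps, object@config@adjacencyMode,
    nrow(object@history), object@bestEpoch
  ))
})

#' Prediction-vs-observation evaluation
#'
#' Mean absolute error, Pearson correlation and the two-sided p-value of the
#' correlation from its exact t-distribution transform with `N - 2` degrees
#' of freedom.
#'
#' @param pred,obs Numeric vectors of equal length (at least 3).
#' @return List with `mae`, `r`, `p`, `n`.
#' @export
evaluatePredictions <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch", call. = FALSE)
  N <- length(pred)
  if (N < 3) stop("need at least 3 pairs", call. = FALSE)
  mae <- mean(abs(pred - obs))
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  r <- stats::cor(pred, obs)
  tstat <- r * sqrt((N - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = N - 2)
  list(mae = mae, r = r, p = p, n = N)
}

#' Nested cross-validated training and evaluation
#'
#' Splits the cohort into `folds` seeded outer folds; within each outer
#' training set, a seeded 90/10 inner split drives per-epoch model
#' selection; predictions on each outer test fold are pooled across folds
#' and summarized with [evaluatePredictions()].
#'
#' @param cohort A preprocessed [ConnectivityCohort-class].
#' @param mconfig A [ModelConfig-class].
#' @param tconfig A [TrainConfig-class]; `tconfig@folds` outer folds and
#'   `tconfig@seed` drive all randomness.
#' @param adjGrad Adjacency gradient rule, see [trainModel()].
#' @param keepModels Return the per-fold [SeverityModel-class] objects.
#' @return List with `metrics` (mae, r, p, n), `predictions` (data.frame of
#'   subject_id, fold, observed, predicted), `foldMetrics`, and optionally
#'   `models`.
#' @export
crossValidate <- function(cohort, mconfig, tconfig,
                          adjGrad = c("straight", "detach"),
                          keepModels = FALSE) {
  adjGrad <- match.arg(adjGrad)
  N <- ncol(cohort)
  if (N < 10) stop("need at least 10 subjects for nested CV", call. = FALSE)
  fold <- makeFolds(N, tconfig@folds, tconfig@seed)
  y <- severityTarget(cohort)
  preds <- rep(NA_real_, N)
  models <- vector("list", tconfig@folds)
  foldMetrics <- vector("list", tconfig@folds)
  for (f in seq_len(tconfig@folds)) {
    testIdx <- which(fold == f)
    outerTrain <- which(fold != f)
    nVal <- max(1L, round(tconfig@innerValFrac * length(outerTrain)))
    valIdx <- withSeed(tconfig@seed + 100L + f,
      sort(sample(outerTrain, nVal)))
    trainIdx <- setdiff(outerTrain, valIdx)
    ftc <- tconfig
    ftc@seed <- tconfig@seed + f
    fit <- trainModel(cohort, trainIdx, valIdx, mconfig, ftc,
      adjGrad = adjGrad)
    preds[testIdx] <- predictScores(connMatrices(cohort)[testIdx],
      fit@params, mconfig)
    foldMetrics[[f]] <- data.frame(
      fold = f, nTest = length(testIdx),
      mae = mean(abs(preds[testIdx] - y[testIdx])),
      bestEpoch = fit@bestEpoch
    )
    if (keepModels) models[[f]] <- fit
  }
  out <- list(
    metrics = evaluatePredictions(preds, y),
    predictions = data.frame(
      subject_id = cohort$subject_id, fold = fold, observed = y,
      predicted = preds
    ),
    foldMetrics = do.call(rbind, foldMetrics)
  )
  if (keepModels) out$models <- models
  out
}
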