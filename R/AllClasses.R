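#' @import methods
#' @importFrom stats cor cov pt sd rnorm runif rbinom
NULL

#' Single-subject connectivity matrix
#'
#' A symmetric weighted network over `n` regions of interest (ROIs) for one
#' subject, tracking how it was estimated (`kind`) and which preprocessing
#' steps (proportional thresholding, per-subject standardization) have been
#' applied.
#'
#' @slot values Numeric `n x n` symmetric matrix.
#' @slot roiLabels Character vector of `n` ROI names.
#' @slot subjectId Subject identifier.
#' @slot kind One of `"pearson"`, `"tikhonov"`, `"raw"`.
#' @slot isThresholded Logical; has proportional thresholding been applied.
#' @slot isStandardized Logical; have retained edges been z-scored.
#' @export
setClass("ConnectivityMatrix",
  slots = c(
    values = "matrix",
    roiLabels = "character",
    subjectId = "character",
    kind = "character",
    isThresholded = "logical",
    isStandardized = "logical"
  )
)

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v) || nrow(v) != ncol(v))
    return("values must be a square numeric matrix")
  if (nrow(v) < 2) return("need at least 2 ROIs")
  if (anyNA(v)) return("values contain missing entries")
  if (max(abs(v - t(v))) > 1e-9) return("values are not symmetric within 1e-9")
  if (length(object@roiLabels) != nrow(v))
    return("roiLabels length must equal the matrix dimension")
  if (!object@kind %in% c("pearson", "tikhonov", "raw"))
    return("kind must be one of 'pearson', 'tikhonov', 'raw'")
  if (object@isThresholded && any(diag(v) != 0))
    return("thresholded matrix must have a zero diagonal")
  TRUE
})

#' Construct a ConnectivityMatrix
#'
#' @param values Symmetric numeric matrix.
#' @param roiLabels ROI names; defaults to the matrix column names or `V1..Vn`.
#' @param subjectId Subject identifier.
#' @param kind Estimation method: `"pearson"`, `"tikhonov"` or `"raw"`.
#' @param isThresholded,isStandardized Preprocessing flags.
#' @return A [ConnectivityMatrix-class] object.
#' @export
ConnectivityMatrix <- function(values, roiLabels = NULL, subjectId = "",
                               kind = "raw", isThresholded = FALSE,
                               isStandardized = FALSE) {
  if (is.null(roiLabels)) {
    roiLabels <- colnames(values)
    if (is.null(roiLabels)) roiLabels <- paste0("V", seq_len(ncol(values)))
  }
  dimnames(values) <- NULL
  new("ConnectivityMatrix",
    values = values, roiLabels = as.character(roiLabels),
    subjectId = as.character(subjectId), kind = kind,
    isThresholded = isThresholded, isStandardized = isStandardized
  )
}

#' Cohort of connectivity matrices with phenotypes
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a single
#' `"connectivity"` assay holding each subject's vectorized `n x n` matrix as
#' a column (`n^2` rows, one column per subject). Phenotypes (subject_id,
#' site, age, sex, severity scores) live in `colData`; ROI labels, the edge
#' kind, preprocessing flags, the modeling target and any simulation ground
#' truth live in `metadata`.
#'
#' @export
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
setClass("ConnectivityCohort", contains = "SummarizedExperiment")

setValidity("ConnectivityCohort", function(object) {
  md <- S4Vectors::metadata(object)
  need <- c("roiLabels", "kind", "isThresholded", "isStandardized")
  if (!all(need %in% names(md)))
    return(paste("metadata must contain", paste(need, collapse = ", ")))
  n <- length(md$roiLabels)
  if (nrow(object) != n * n)
    return("assay must have nROIs^2 rows (vectorized matrices)")
  cd <- SummarizedExperiment::colData(object)
  must <- c("subject_id", "site", "age", "sex")
  if (!all(must %in% colnames(cd)))
    return(paste("colData must contain", paste(must, collapse = ", ")))
  if (anyDuplicated(cd$subject_id)) return("subject_id values must be unique")
  TRUE
})

#' Architecture configuration of the severity-prediction network
#'
#' @slot nROIs Number of graph nodes (ROIs).
#' @slot nMaps Feature maps per edge-to-edge / edge-to-node layer (constant
#'   across layers).
#' @slot nE2ELayers Number of stacked edge-to-edge layers.
#' @slot nAttLayers Number of self-attention pooling layers.
#' @slot pAtt Hidden width of the attention-score GCN stack.
#' @slot poolRatio Fraction of nodes kept by each pooling layer.
#' @slot adjacencyMode `"identity"`, `"e2e"` or `"averaging"`.
#' @slot mlpSizes Hidden-layer widths of the prediction head.
#' @slot leakySlope Negative slope of the leaky ReLU activations.
#' @export
setClass("ModelConfig",
  slots = c(
    nROIs = "integer", nMaps = "integer", nE2ELayers = "integer",
    nAttLayers = "integer", pAtt = "integer", poolRatio = "numeric",
    adjacencyMode = "character", mlpSizes = "integer", leakySlope = "numeric"
  )
)

setValidity("ModelConfig", function(object) {
  if (object@nROIs < 2) return("nROIs must be >= 2")
  if (object@nMaps < 1) return("nMaps must be >= 1")
  if (object@nE2ELayers < 1) return("nE2ELayers must be >= 1")
  if (object@nAttLayers < 1) return("nAttLayers must be >= 1")
  if (object@poolRatio <= 0 || object@poolRatio > 1)
    return("poolRatio must be in (0, 1]")
  if (!object@adjacencyMode %in% c("identity", "e2e", "averaging"))
    return("adjacencyMode must be 'identity', 'e2e' or 'averaging'")
  if (length(object@mlpSizes) < 1) return("mlpSizes must be non-empty")
  TRUE
})

#' Construct a ModelConfig
#'
#' Defaults follow the reference architecture: two edge-to-edge layers, two
#' attention-pooling layers with a width-1 score stack, pooling ratio 1/2,
#' identity adjacency embedding, prediction head of sizes 128 and 64, and
#' leaky slope 1/3. The number of feature maps `nMaps` is a free width
#' parameter (default 32).
#'
#' @param nROIs Number of ROIs (graph nodes).
#' @param nMaps Feature maps per extractor layer.
#' @param nE2ELayers Stacked edge-to-edge layers.
#' @param nAttLayers Self-attention pooling layers.
#' @param pAtt Hidden width of the score GCN stack.
#' @param poolRatio Fraction of nodes retained per pooling layer.
#' @param adjacencyMode Adjacency embedding variant.
#' @param mlpSizes Hidden sizes of the prediction head.
#' @param leakySlope Leaky ReLU negative slope.
#' @return A [ModelConfig-class] object.
#' @export
modelConfig <- function(nROIs, nMaps = 32L, nE2ELayers = 2L, nAttLayers = 2L,
                        pAtt = 1L, poolRatio = 0.5,
                        adjacencyMode = c("identity", "e2e", "averaging"),
                        mlpSizes = c(128L, 64L), leakySlope = 1 / 3) {
  adjacencyMode <- match.arg(adjacencyMode)
  new("ModelConfig",
    nROIs = as.integer(nROIs), nMaps = as.integer(nMaps),
    nE2ELayers = as.integer(nE2ELayers), nAttLayers = as.integer(nAttLayers),
    pAtt = as.integer(pAtt), poolRatio = poolRatio,
    adjacencyMode = adjacencyMode, mlpSizes = as.integer(mlpSizes),
    leakySlope = leakySlope
  )
}

#' Optimization configuration
#'
#' Defaults follow the reference training recipe: SGD with momentum 0.9,
#' initial learning rate 1e-5 annealed to zero by a cosine schedule over 1000
#' epochs, mini-batches of 8, weight decay 1e-4, mean-squared-error loss,
#' 5-fold outer cross-validation with an inner 90/10 train/validation split.
#'
#' @slot lr0 Initial learning rate.
#' @slot momentum SGD momentum coefficient.
#' @slot epochs Total training epochs (the cosine period).
#' @slot batchSize Mini-batch size.
#' @slot weightDecay L2 weight-decay coefficient.
#' @slot folds Outer cross-validation folds.
#' @slot innerValFrac Fraction of outer-train held out for model selection.
#' @slot clipNorm Maximum L2 norm of a batch gradient; `Inf` disables
#'   clipping (the default). A finite value rescales exploding gradients,
#'   stabilizing momentum SGD at higher learning rates.
#' @slot seed Base random seed.
#' @export
setClass("TrainConfig",
  slots = c(
    lr0 = "numeric", momentum = "numeric", epochs = "integer",
    batchSize = "integer", weightDecay = "numeric", folds = "integer",
    innerValFrac = "numeric", clipNorm = "numeric", seed = "integer"
  )
)

setValidity("TrainConfig", function(object) {
  if (object@lr0 <= 0) return("lr0 must be positive")
  if (object@epochs < 1) return("epochs must be >= 1")
  if (object@batchSize < 1) return("batchSize must be >= 1")
  if (object@weightDecay < 0) return("weightDecay must be >= 0")
  if (object@innerValFrac <= 0 || object@innerValFrac >= 1)
    return("innerValFrac must be in (0, 1)")
  if (object@folds < 2) return("folds must be >= 2")
  if (object@clipNorm <= 0) return("clipNorm must be positive")
  TRUE
})

#' Construct a TrainConfig
#'
#' @param lr0 Initial learning rate.
#' @param momentum Momentum coefficient.
#' @param epochs Total epochs (cosine schedule period).
#' @param batchSize Mini-batch size.
#' @param weightDecay Weight-decay coefficient.
#' @param folds Outer CV folds.
#' @param innerValFrac Inner validation fraction.
#' @param clipNorm Max batch-gradient L2 norm (`Inf` = no clipping).
#' @param seed Base seed controlling all randomness.
#' @return A [TrainConfig-class] object.
#' @export
trainConfig <- function(lr0 = 1e-5, momentum = 0.9, epochs = 1000L,
                        batchSize = 8L, weightDecay = 1e-4, folds = 5L,
                        innerValFrac = 0.1, clipNorm = Inf, seed = 1L) {
  new("TrainConfig",
    lr0 = lr0, momentum = momentum, epochs = as.integer(epochs),
    batchSize = as.integer(batchSize), weightDecay = weightDecay,
    folds = as.integer(folds), innerValFrac = innerValFrac,
    clipNorm = clipNorm, seed = as.integer(seed)
  )
}

#' Trained severity-prediction model
#'
#' @slot config The [ModelConfig-class] used.
#' @slot params Named list of parameter arrays.
#' @slot history Per-epoch training log (loss, learning rate, validation MAE).
#' @slot bestEpoch Epoch whose parameters are stored (best validation MAE).
#' @export
setClass("SeverityModel",
  slots = c(
    config = "ModelConfig", params = "list",
    history = "data.frame", bestEpoch = "integer"
  )
)
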