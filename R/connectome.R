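#' Pearson correlation connectivity
#'
#' Builds a functional connectivity matrix from ROI time series as the
#' pairwise Pearson correlation of demeaned series:
#' \eqn{c_{ij} = \tilde t_i^\top \tilde t_j /
#' \sqrt{(\tilde t_i^\top \tilde t_i)(\tilde t_j^\top \tilde t_j)}}.
#'
#' @param ts Numeric matrix, rows = timepoints, columns = ROIs (column names
#'   become ROI labels).
#' @param subjectId Subject identifier.
#' @return A [ConnectivityMatrix-class] with `kind = "pearson"`, entries in
#'   \[-1, 1\] and unit diagonal.
#' @export
#' @examples
#' ts <- matrix(rnorm(80), 20, 4)
#' pearsonConnectivity(ts)
pearsonConnectivity <- function(ts, subjectId = "") {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2) stop("need at least 2 timepoints", call. = FALSE)
  if (ncol(ts) < 2) stop("need at least 2 ROIs", call. = FALSE)
  if (anyNA(ts)) stop("time series contain missing values", call. = FALSE)
  v <- apply(ts, 2, stats::var)
  if (any(v == 0)) {
    bad <- colnames(ts)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop("degenerate (zero-variance) ROI series: ",
      paste(bad, collapse = ", "), call. = FALSE)
  }
  cc <- stats::cor(ts)
  cc <- (cc + t(cc)) / 2 # enforce exact symmetry
  ConnectivityMatrix(cc, roiLabels = colnames(ts), subjectId = subjectId,
    kind = "pearson")
}

#' Tikhonov-regularized precision matrix from a covariance
#'
#' @param C Symmetric empirical covariance matrix.
#' @param rho Nonnegative ridge added to the diagonal before inversion.
#' @return The precision matrix \eqn{(C + \rho I)^{-1}}.
#' @export
tikhonovPrecision <- function(C, rho = 0.1) {
  checkSymmetric(C, tol = 1e-8, what = "covariance")
  if (rho < 0) stop("rho must be >= 0", call. = FALSE)
  M <- C + diag(rho, nrow(C))
  kap <- kappa(M, exact = FALSE)
  P <- tryCatch(solve(M), error = function(e) {
    stop(sprintf(
      "C + rho*I is numerically singular (condition number %.3g): %s",
      kap, conditionMessage(e)), call. = FALSE)
  })
  (P + t(P)) / 2
}

#' Tikhonov partial-correlation connectivity
#'
#' Estimates connectivity as the regularized inverse of the empirical time
#' series covariance, \eqn{P = (C + \rho I)^{-1}}, which damps indirect
#' (shared-neighbour) connections relative to plain correlation. The
#' empirical covariance uses 1/T normalization of demeaned outer products.
#'
#' @param ts Numeric matrix, rows = timepoints, columns = ROIs.
#' @param rho Regularization parameter (default 0.1).
#' @param partialCor If `TRUE`, rescale to the partial-correlation sign
#'   convention \eqn{-P_{ij}/\sqrt{P_{ii} P_{jj}}} (diagonal set to 1). The
#'   default keeps the precision matrix itself.
#' @param subjectId Subject identifier.
#' @return A [ConnectivityMatrix-class] with `kind = "tikhonov"`.
#' @export
tikhonovConnectivity <- function(ts, rho = 0.1, partialCor = FALSE,
                                 subjectId = "") {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2) stop("need at least 2 timepoints", call. = FALSE)
  if (anyNA(ts)) stop("time series contain missing values", call. = FALSE)
  tc <- scale(ts, center = TRUE, scale = FALSE)
  C <- crossprod(tc) / nrow(ts)
  P <- tikhonovPrecision(C, rho)
  if (partialCor) {
    d <- sqrt(diag(P))
    P <- -P / outer(d, d)
    diag(P) <- 1
  }
  ConnectivityMatrix(P, roiLabels = colnames(ts), subjectId = subjectId,
    kind = "tikhonov")
}

## core thresholding on a plain symmetric matrix
thresholdCore <- function(v, sparsity) {
  if (sparsity <= 0 || sparsity > 1)
    stop("sparsity must be in (0, 1]", call. = FALSE)
  n <- nrow(v)
  pairs <- upperTriPairs(n)
  vals <- v[pairs]
  m <- floor(sparsity * n * (n - 1) / 2)
  out <- matrix(0, n, n)
  if (m > 0) {
    ## rank by |value|, ties broken by lexicographic (i, j) position
    ord <- order(-abs(vals), pairs[, 1], pairs[, 2])
    keep <- ord[seq_len(m)]
    keep <- keep[abs(vals[keep]) > 0] # an all-zero matrix retains nothing
    out[pairs[keep, , drop = FALSE]] <- vals[keep]
    out[pairs[keep, c(2, 1), drop = FALSE]] <- vals[keep]
  }
  out
}

#' @describeIn proportionalThreshold Threshold a single matrix: zeroes the
#'   diagonal and keeps the `floor(sparsity * n(n-1)/2)` upper-triangle
#'   entries of largest absolute value (signed weights retained, mirrored to
#'   the lower triangle). Ties at the cutoff magnitude are broken by
#'   lexicographic (i, j) position for platform-independent results.
#' @export
setMethod("proportionalThreshold", "ConnectivityMatrix",
  function(x, sparsity = 0.05, ...) {
    out <- thresholdCore(x@values, sparsity)
    initialize(x, values = out, isThresholded = TRUE, isStandardized = FALSE)
  }
)

#' @describeIn proportionalThreshold Threshold every matrix of a cohort.
#' @export
setMethod("proportionalThreshold", "ConnectivityCohort",
  function(x, sparsity = 0.05, ...) {
    a <- SummarizedExperiment::assay(x, "connectivity")
    n <- nROIs(x)
    for (k in seq_len(ncol(a)))
      a[, k] <- as.vector(thresholdCore(matrix(a[, k], n, n), sparsity))
    SummarizedExperiment::assay(x, "connectivity") <- a
    md <- S4Vectors::metadata(x)
    md$isThresholded <- TRUE
    md$isStandardized <- FALSE
    md$sparsity <- sparsity
    S4Vectors::metadata(x) <- md
    x
  }
)

## z-score retained (nonzero) upper-triangle entries; population sd
standardizeCore <- function(v) {
  n <- nrow(v)
  pairs <- upperTriPairs(n)
  vals <- v[pairs]
  idx <- which(vals != 0)
  if (length(idx) < 2)
    stop("need at least 2 retained edges to standardize", call. = FALSE)
  x <- vals[idx]
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0)
    stop("all retained edge values are equal; zero variance", call. = FALSE)
  vals[idx] <- (x - mu) / s
  out <- matrix(0, n, n)
  out[pairs] <- vals
  out[pairs[, c(2, 1)]] <- vals
  out
}

#' @describeIn standardizeMatrix Z-score the retained edges of one subject:
#'   nonzero upper-triangle entries are centred and scaled to unit
#'   *population* standard deviation (zeros and the diagonal are untouched,
#'   symmetry preserved).
#' @export
setMethod("standardizeMatrix", "ConnectivityMatrix", function(x, ...) {
  if (!x@isThresholded)
    stop("standardizeMatrix expects a thresholded matrix", call. = FALSE)
  initialize(x, values = standardizeCore(x@values), isStandardized = TRUE)
})

#' @describeIn standardizeMatrix Standardize every subject of a cohort.
#' @export
setMethod("standardizeMatrix", "ConnectivityCohort", function(x, ...) {
  if (!isThresholded(x))
    stop("standardizeMatrix expects a thresholded cohort", call. = FALSE)
  a <- SummarizedExperiment::assay(x, "connectivity")
  n <- nROIs(x)
  for (k in seq_len(ncol(a)))
    a[, k] <- as.vector(standardizeCore(matrix(a[, k], n, n)))
  SummarizedExperiment::assay(x, "connectivity") <- a
  md <- S4Vectors::metadata(x)
  md$isStandardized <- TRUE
  S4Vectors::metadata(x) <- md
  x
})

#' Build the covariate design matrix used for residualization
#'
#' Site is one-hot encoded with the first level dropped; sex becomes a 0/1
#' indicator; age enters linearly. An intercept is always included.
#'
#' @param pheno Phenotype data.frame.
#' @param covariates Subset of `c("site", "age", "sex")`.
#' @return Numeric design matrix with one row per subject.
#' @keywords internal
covariateDesign <- function(pheno, covariates) {
  X <- matrix(1, nrow(pheno), 1, dimnames = list(NULL, "(Intercept)"))
  if ("site" %in% covariates) {
    site <- factor(pheno$site)
    if (nlevels(site) > 1) {
      S <- stats::model.matrix(~site)[, -1, drop = FALSE]
      X <- cbind(X, S)
    }
  }
  if ("age" %in% covariates) X <- cbind(X, age = as.numeric(pheno$age))
  if ("sex" %in% covariates) {
    sx <- pheno$sex
    if (!is.numeric(sx)) sx <- as.integer(factor(sx)) - 1L
    X <- cbind(X, sex = as.numeric(sx))
  }
  X
}

#' Remove site and covariate effects from cohort edges
#'
#' For every edge position retained in at least one subject, fits an
#' ordinary-least-squares regression of the edge value on an intercept, site
#' indicators and/or age and sex, using `fitRows` only, then replaces values
#' for *all* subjects by their residuals from that fit. Positions that are
#' zero in every subject stay exactly zero. Fitting on the whole sample
#' mirrors harmonization applied prior to training; pass training-fold
#' indices as `fitRows` for the leakage-free variant.
#'
#' @param x A [ConnectivityCohort-class].
#' @param covariates Character subset of `c("site", "age", "sex")`.
#' @param fitRows Subject indices used to estimate the regression
#'   coefficients (default: all subjects).
#' @return The cohort with residualized edge values.
#' @export
residualizeCovariates <- function(x, covariates = c("site", "age", "sex"),
                                  fitRows = seq_len(ncol(x))) {
  stopifnot(is(x, "ConnectivityCohort"))
  covariates <- match.arg(covariates, several.ok = TRUE)
  ph <- as.data.frame(SummarizedExperiment::colData(x))
  X <- covariateDesign(ph, covariates)
  if (length(fitRows) < ncol(X) + 2)
    stop("need at least ", ncol(X) + 2, " fit rows for ", ncol(X),
      " regressors", call. = FALSE)
  Xf <- X[fitRows, , drop = FALSE]
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf)) {
    bad <- colnames(Xf)[qrX$pivot[(qrX$rank + 1):ncol(Xf)]]
    stop("rank-deficient covariate design; collinear columns: ",
      paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- nROIs(x)
  a <- SummarizedExperiment::assay(x, "connectivity")
  pairs <- upperTriPairs(n)
  flat <- pairs[, 1] + (pairs[, 2] - 1L) * n # upper-tri flat indices
  E <- t(a[flat, , drop = FALSE]) # subjects x edges
  keep <- which(colSums(E != 0) > 0)
  if (length(keep)) {
    beta <- qr.coef(qrX, E[fitRows, keep, drop = FALSE])
    E[, keep] <- E[, keep, drop = FALSE] - X %*% beta
  }
  for (k in seq_len(ncol(a))) {
    m <- matrix(0, n, n)
    m[pairs] <- E[k, ]
    m[pairs[, c(2, 1)]] <- E[k, ]
    a[, k] <- as.vector(m)
  }
  SummarizedExperiment::assay(x, "connectivity") <- a
  md <- S4Vectors::metadata(x)
  md$residualized <- covariates
  S4Vectors::metadata(x) <- md
  x
}

#' Full connectome preprocessing pipeline
#'
#' Applies proportional thresholding, per-subject standardization and
#' (optionally) covariate residualization, in that order.
#'
#' @param x A [ConnectivityCohort-class] of raw connectivity matrices.
#' @param sparsity Retained edge fraction (default 0.05).
#' @param covariates `NULL` for no residualization, otherwise a subset of
#'   `c("site", "age", "sex")`.
#' @param fitRows Rows used to fit residualization coefficients.
#' @return The preprocessed cohort, ready for the model.
#' @export
buildCohort <- function(x, sparsity = 0.05, covariates = NULL,
                        fitRows = seq_len(ncol(x))) {
  x <- proportionalThreshold(x, sparsity)
  x <- standardizeMatrix(x)
  if (!is.null(covariates))
    x <- residualizeCovariates(x, covariates, fitRows)
  x
}

## ---- ConnectivityMatrix accessors ----

#' @describeIn ConnectivityMatrix-class Raw matrix values.
#' @param ... Unused.
#' @export
setMethod("connValues", "ConnectivityMatrix", function(x, ...) x@values)

#' @describeIn ConnectivityMatrix-class Number of ROIs.
#' @export
setMethod("nROIs", "ConnectivityMatrix", function(x) nrow(x@values))

#' @describeIn ConnectivityMatrix-class ROI labels.
#' @export
setMethod("roiLabels", "ConnectivityMatrix", function(x) x@roiLabels)

#' @describeIn ConnectivityMatrix-class Thresholding flag.
#' @export
setMethod("isThresholded", "ConnectivityMatrix", function(x) x@isThresholded)

#' @describeIn ConnectivityMatrix-class Standardization flag.
#' @export
setMethod("isStandardized", "ConnectivityMatrix", function(x) x@isStandardized)

#' @describeIn ConnectivityMatrix-class Estimation method.
#' @export
setMethod("edgeKind", "ConnectivityMatrix", function(x) x@kind)

#' @describeIn ConnectivityMatrix-class Compact display.
#' @export
setMethod("show", "ConnectivityMatrix", function(object) {
  n <- nrow(object@values)
  nz <- sum(object@values[upper.tri(object@values)] != 0)
  cat(sprintf(
    "ConnectivityMatrix '%s': %d ROIs, kind=%s, %d nonzero edges%s%s\n",
    object@subjectId, n, object@kind, nz,
    if (object@isThresholded) ", thresholded" else "",
    if (object@isStandardized) ", standardized" else ""
  ))
})
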