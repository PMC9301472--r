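#' Extract learned node embeddings
#'
#' Returns the edge-to-node layer output (`n x d`) of a trained model for
#' one connectivity matrix — the node-feature representation whose
#' relationship with graph-theoretic measures the three-level correlation
#' analysis quantifies.
#'
#' @param g Preprocessed connectivity matrix.
#' @param model A [SeverityModel-class] (or a list with `params`; then pass
#'   `config`).
#' @param config Optional [ModelConfig-class] when `model` is a raw
#'   parameter list.
#' @return Numeric `n x d` matrix.
#' @export
extractNodeEmbeddings <- function(g, model, config = NULL) {
  if (is(model, "SeverityModel")) {
    params <- model@params
    config <- model@config
  } else {
    params <- model
    if (is.null(config)) stop("config required with a raw parameter list",
      call. = FALSE)
  }
  modelForward(g, params, config, intermediates = TRUE)$state$E
}

dropConstantCols <- function(X, what) {
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0))
    stop("all ", what, " columns are constant", call. = FALSE)
  if (any(sds == 0))
    warning("skipping ", sum(sds == 0), " constant ", what, " column(s)")
  X[, sds > 0, drop = FALSE]
}

#' Level 1: best pairwise correlation per measure
#'
#' For each graph-measure column, the maximum Pearson correlation over all
#' embedding columns.
#'
#' @param Xgm Node-measure matrix (`n x p`).
#' @param Xnf Node-embedding matrix (`n x q`).
#' @return Numeric vector of length `p` (named if `Xgm` has column names).
#' @export
level1PairwiseMax <- function(Xgm, Xnf) {
  Xgm <- as.matrix(Xgm)
  Xnf <- dropConstantCols(as.matrix(Xnf), "embedding")
  out <- apply(Xgm, 2, function(xm) {
    if (stats::sd(xm) == 0) return(NA_real_)
    max(as.vector(stats::cor(xm, Xnf)))
  })
  out
}

## symmetric inverse square root with ridge stabilization
invSqrtSym <- function(S, ridge = 1e-8) {
  S <- S + diag(ridge, nrow(S))
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) <= 0)
    stop("within-set covariance is singular; increase the ridge",
      call. = FALSE)
  es$vectors %*% (t(es$vectors) / sqrt(es$values))
}

#' Level 2: per-measure canonical correlation
#'
#' For each measure column, the maximal correlation achievable between that
#' measure and a linear combination of the embedding columns — the multiple
#' correlation coefficient, equal to the square root of the R-squared of
#' regressing the measure on the embeddings.
#'
#' @param Xgm Node-measure matrix (`n x p`).
#' @param Xnf Node-embedding matrix (`n x q`).
#' @param ridge Ridge added to the within-set covariance (default 1e-8).
#' @return Numeric vector of length `p`.
#' @export
level2PerMeasureCCA <- function(Xgm, Xnf, ridge = 1e-8) {
  Xgm <- as.matrix(Xgm)
  Xnf <- dropConstantCols(as.matrix(Xnf), "embedding")
  n <- nrow(Xgm)
  Yc <- scale(Xnf, center = TRUE, scale = FALSE)
  S22 <- crossprod(Yc) / (n - 1) + diag(ridge, ncol(Yc))
  apply(Xgm, 2, function(xm) {
    if (stats::sd(xm) == 0) return(NA_real_)
    xc <- xm - mean(xm)
    s12 <- crossprod(xc, Yc) / (n - 1) # 1 x q
    s11 <- sum(xc^2) / (n - 1)
    r2 <- as.numeric(s12 %*% solve(S22, t(s12))) / s11
    sqrt(max(min(r2, 1), 0))
  })
}

#' Level 3: full canonical correlation between the two domains
#'
#' First canonical correlation between the measures and the embeddings, via
#' singular value decomposition of the whitened cross-covariance
#' `S11^{-1/2} S12 S22^{-1/2}` (ridge-stabilized within-set covariances).
#'
#' @param Xgm Node-measure matrix (`n x p`).
#' @param Xnf Node-embedding matrix (`n x q`).
#' @param ridge Ridge added to both within-set covariances (default 1e-8).
#' @return List with `correlation` (scalar, the largest singular value,
#'   clipped to \[0, 1\]), and weight vectors `wgm`, `wnf`.
#' @export
level3FullCCA <- function(Xgm, Xnf, ridge = 1e-8) {
  Xgm <- dropConstantCols(as.matrix(Xgm), "measure")
  Xnf <- dropConstantCols(as.matrix(Xnf), "embedding")
  n <- nrow(Xgm)
  if (nrow(Xnf) != n) stop("row counts differ", call. = FALSE)
  Xc <- scale(Xgm, center = TRUE, scale = FALSE)
  Yc <- scale(Xnf, center = TRUE, scale = FALSE)
  S11 <- crossprod(Xc) / (n - 1)
  S22 <- crossprod(Yc) / (n - 1)
  S12 <- crossprod(Xc, Yc) / (n - 1)
  W1 <- invSqrtSym(S11, ridge)
  W2 <- invSqrtSym(S22, ridge)
  K <- W1 %*% S12 %*% W2
  sv <- svd(K, nu = 1, nv = 1)
  list(
    correlation = min(sv$d[1], 1),
    wgm = as.vector(W1 %*% sv$u[, 1]),
    wnf = as.vector(W2 %*% sv$v[, 1])
  )
}

#' Three-level correlation analysis across a cohort
#'
#' Runs, for every subject, the three analysis levels relating the model's
#' node embeddings (domain 1) to the eight graph-theoretic nodal measures
#' (domain 2): (1) best pairwise correlation per measure, (2) per-measure
#' canonical correlation against all embeddings, (3) the full canonical
#' correlation between the two domains. Per-subject values are summarized
#' as mean and standard deviation across subjects.
#'
#' @param cohort A preprocessed [ConnectivityCohort-class].
#' @param model A trained [SeverityModel-class].
#' @param ridge Ridge stabilization for the CCA levels.
#' @return List with `perSubject` (long data.frame: subject_id, level,
#'   measure, value) and `summary` (mean and sd per level/measure).
#' @export
ccaNodeAnalysis <- function(cohort, model, ridge = 1e-8) {
  gs <- connMatrices(cohort)
  ids <- cohort$subject_id
  rows <- vector("list", length(gs))
  for (k in seq_along(gs)) {
    Xnf <- extractNodeEmbeddings(gs[[k]], model)
    Xgm <- nodeMeasuresCore(1 * (abs(gs[[k]]) > 0))
    ## constant columns (e.g. a measure that is identical across nodes on a
    ## very sparse graph) carry no correlational information and are
    ## excluded per subject without the per-call warnings
    l1 <- suppressWarnings(level1PairwiseMax(Xgm, Xnf))
    l2 <- suppressWarnings(level2PerMeasureCCA(Xgm, Xnf, ridge))
    l3 <- suppressWarnings(level3FullCCA(Xgm, Xnf, ridge)$correlation)
    rows[[k]] <- rbind(
      data.frame(subject_id = ids[k], level = "level1",
        measure = measureNames, value = unname(l1)),
      data.frame(subject_id = ids[k], level = "level2",
        measure = measureNames, value = unname(l2)),
      data.frame(subject_id = ids[k], level = "level3", measure = "all",
        value = l3)
    )
  }
  perSubject <- do.call(rbind, rows)
  agg <- stats::aggregate(value ~ level + measure, data = perSubject,
    FUN = function(v) c(mean = mean(v, na.rm = TRUE),
      sd = stats::sd(v, na.rm = TRUE)))
  summary <- data.frame(
    level = agg$level, measure = agg$measure,
    mean = agg$value[, "mean"], sd = agg$value[, "sd"]
  )
  list(perSubject = perSubject, summary = summary)
}

#' Gradient saliency map for one subject
#'
#' The partial derivative of the predicted severity score with respect to
#' every input connectivity entry, computed analytically by
#' backpropagation at the model's actual (preprocessed) input and
#' symmetrized as `(PD + PD^T) / 2` since edges are undirected. The binary
#' pooling adjacency is locally constant in the input, so the exact local
#' gradient is used.
#'
#' @param g Preprocessed connectivity matrix.
#' @param model A trained [SeverityModel-class].
#' @return Numeric `n x n` symmetric saliency matrix.
#' @export
saliencyMap <- function(g, model) {
  stopifnot(is(model, "SeverityModel"))
  fw <- modelForward(g, model@params, model@config, intermediates = TRUE)
  bw <- modelBackward(fw, model@params, model@config, dy = 1,
    adjGrad = "detach")
  (bw$dInput + t(bw$dInput)) / 2
}

#' Group-level saliency and top-edge table
#'
#' Averages per-subject saliency maps element-wise into a group
#' contribution matrix, ranks undirected edges by absolute contribution and
#' reports the top fraction.
#'
#' @param maps List of per-subject `n x n` saliency matrices.
#' @param keepFraction Fraction of upper-triangle edges to report (default
#'   0.10, i.e. the top 10% of edges by magnitude); at least one edge is
#'   always reported.
#' @param roiLabels Optional ROI names for the edge table.
#' @return List with `map` (the group-mean matrix) and `edges` (data.frame
#'   `region1`, `region2`, `pd_value`, sorted by decreasing `|pd_value|`).
#' @export
groupSaliency <- function(maps, keepFraction = 0.1, roiLabels = NULL) {
  if (!length(maps)) stop("need at least one saliency map", call. = FALSE)
  if (keepFraction <= 0 || keepFraction > 1)
    stop("keepFraction must be in (0, 1]", call. = FALSE)
  G <- Reduce(`+`, maps) / length(maps)
  n <- nrow(G)
  if (is.null(roiLabels)) roiLabels <- paste0("V", seq_len(n))
  pairs <- upperTriPairs(n)
  vals <- G[pairs]
  nKeep <- max(1L, floor(keepFraction * nrow(pairs)))
  ord <- order(-abs(vals), pairs[, 1], pairs[, 2])[seq_len(nKeep)]
  list(
    map = G,
    edges = data.frame(
      region1 = roiLabels[pairs[ord, 1]],
      region2 = roiLabels[pairs[ord, 2]],
      pd_value = vals[ord]
    )
  )
}

#' Cohort-level saliency analysis
#'
#' Computes a saliency map for each subject with [saliencyMap()] and
#' aggregates them with [groupSaliency()].
#'
#' @param cohort A preprocessed [ConnectivityCohort-class].
#' @param model A trained [SeverityModel-class].
#' @param keepFraction Edge fraction for the top-edge table.
#' @return As [groupSaliency()], plus `perSubject` (list of maps).
#' @export
cohortSaliency <- function(cohort, model, keepFraction = 0.1) {
  maps <- lapply(connMatrices(cohort), saliencyMap, model = model)
  out <- groupSaliency(maps, keepFraction, roiLabels(cohort))
  out$perSubject <- maps
  out
}
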