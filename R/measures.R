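#' @importFrom igraph graph_from_adjacency_matrix degree transitivity
#'   betweenness eigen_centrality coreness components induced_subgraph
#'   subgraph_centrality local_efficiency ecount V
NULL

measureNames <- c(
  "degree", "clustering", "local_efficiency", "betweenness",
  "eigenvector", "subgraph", "flow", "kcore"
)

## flow coefficient on a binary adjacency: the fraction of a node's
## neighbour pairs that are *not* directly connected, i.e. the fraction of
## centred 2-paths that are shortest paths (1 - clustering on simple graphs);
## 0 for degree < 2
flowCoefficient <- function(B) {
  n <- nrow(B)
  deg <- rowSums(B)
  out <- numeric(n)
  for (i in which(deg >= 2)) {
    nb <- which(B[i, ] > 0)
    sub <- B[nb, nb, drop = FALSE]
    npairs <- deg[i] * (deg[i] - 1) / 2
    closed <- sum(sub[upper.tri(sub)] > 0)
    out[i] <- (npairs - closed) / npairs
  }
  out
}

nodeMeasuresCore <- function(B) {
  n <- nrow(B)
  diag(B) <- 0
  gr <- igraph::graph_from_adjacency_matrix(B, mode = "undirected")

  deg <- as.numeric(igraph::degree(gr))
  clus <- igraph::transitivity(gr, type = "local", isolates = "zero")
  clus[is.na(clus)] <- 0
  leff <- suppressWarnings(igraph::local_efficiency(gr))
  leff[is.na(leff)] <- 0
  btw <- as.numeric(igraph::betweenness(gr, directed = FALSE,
    normalized = FALSE))

  ## eigenvector centrality: principal eigenvector of the largest connected
  ## component, scaled to unit 2-norm; other components get 0
  ev <- numeric(n)
  if (igraph::ecount(gr) > 0) {
    comp <- igraph::components(gr)
    big <- which.max(comp$csize)
    mem <- which(comp$membership == big)
    if (length(mem) > 1) {
      sub <- igraph::induced_subgraph(gr, mem)
      v <- igraph::eigen_centrality(sub, directed = FALSE)$vector
      v <- abs(v)
      ev[mem] <- v / sqrt(sum(v^2))
    }
  }

  subg <- as.numeric(igraph::subgraph_centrality(gr, diag = TRUE))
  flow <- flowCoefficient(B)
  kcore <- as.numeric(igraph::coreness(gr))

  out <- cbind(deg, clus, leff, btw, ev, subg, flow, kcore)
  colnames(out) <- measureNames
  out
}

#' @describeIn nodeMeasures Eight graph-theory nodal measures of a
#'   thresholded connectivity matrix, computed on the binarized graph
#'   `B = 1(|values| > 0)` (negative retained weights are binarized by
#'   absolute value; no self-loops). Columns: degree, local clustering
#'   coefficient, local efficiency, betweenness centrality (unnormalized,
#'   fractional credit for tied geodesics), eigenvector centrality
#'   (principal eigenvector of the largest component, unit 2-norm),
#'   subgraph centrality (`[exp(B)]_ii`), flow coefficient (fraction of a
#'   node's neighbour pairs not directly connected) and k-core number. On
#'   disconnected graphs, path-based measures are per component.
#' @export
setMethod("nodeMeasures", "ConnectivityMatrix", function(x, ...) {
  if (!x@isThresholded)
    stop("nodeMeasures expects a thresholded matrix", call. = FALSE)
  out <- nodeMeasuresCore(1 * (abs(x@values) > 0))
  rownames(out) <- x@roiLabels
  out
})

#' @describeIn nodeMeasures Measures of a plain 0/1 (or weighted, binarized
#'   by `|value| > 0`) adjacency matrix.
#' @export
setMethod("nodeMeasures", "matrix", function(x, ...) {
  checkSymmetric(x, tol = 1e-9, what = "adjacency")
  nodeMeasuresCore(1 * (abs(x) > 0))
})

#' Per-subject nodal measures of a cohort
#'
#' @param cohort A thresholded [ConnectivityCohort-class].
#' @return List of `n x 8` measure matrices, one per subject.
#' @export
cohortNodeMeasures <- function(cohort) {
  if (!isThresholded(cohort))
    stop("cohortNodeMeasures expects a thresholded cohort", call. = FALSE)
  lapply(connMatrices(cohort), function(m) nodeMeasuresCore(1 * (abs(m) > 0)))
}
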