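## pre-activation of one edge-to-edge layer.
## fmaps: n x n x dIn, r/c: n x dIn x dOut. A column-major n x n x d array
## is reinterpreted as the n x (n d) block matrix [f_1 | ... | f_d] at zero
## cost, turning the per-map kernel sums into single matrix products.
e2ePre <- function(fmaps, r, c) {
  n <- dim(fmaps)[1]
  dIn <- dim(fmaps)[3]
  dOut <- dim(r)[3]
  fw <- fmaps
  dim(fw) <- c(n, n * dIn)
  rmat <- r
  dim(rmat) <- c(n * dIn, dOut)
  Rrow <- fw %*% rmat # Rrow[i,b] = sum_a sum_k f[i,k,a] r[k,a,b]
  Ccol <- matrix(0, n, dOut)
  for (a in seq_len(dIn)) {
    fa <- fw[, ((a - 1L) * n + 1L):(a * n), drop = FALSE]
    Ccol <- Ccol + crossprod(fa, matrix(c[, a, ], n, dOut))
  }
  ## pre[i,j,b] = Rrow[i,b] + Ccol[j,b], broadcast without per-map loops
  pre <- Rrow[, rep(seq_len(dOut), each = n), drop = FALSE] +
    rep(as.vector(Ccol), each = n)
  dim(pre) <- c(n, n, dOut)
  pre
}

#' Edge-to-edge convolution layer
#'
#' Propagates edge features over the line graph with a cross-shaped kernel:
#' the output for edge (i, j) in map b is
#' `lReLU( sum_a sum_k r[k,a,b] f[i,k,a] + c[k,a,b] f[k,j,a] )`,
#' i.e. a row kernel applied along node i's row and a column kernel along
#' node j's column, summed over input maps.
#'
#' @param fmaps Input edge-feature tensor, `n x n x d_in` array.
#' @param r,c Row and column kernels, `n x d_in x d_out` arrays.
#' @param slope Leaky ReLU slope.
#' @return Output tensor, `n x n x d_out`.
#' @export
e2eForward <- function(fmaps, r, c, slope = 1 / 3) {
  if (!identical(dim(fmaps)[c(1, 3)], dim(r)[c(1, 2)]) ||
    !identical(dim(r), dim(c)))
    stop("edge-to-edge kernel shapes do not match the input tensor",
      call. = FALSE)
  leakyRelu(e2ePre(fmaps, r, c), slope)
}

## pre-activation of the edge-to-node layer; w: n x dIn x dOut
e2nPre <- function(fmaps, w) {
  n <- dim(fmaps)[1]
  dIn <- dim(fmaps)[3]
  dOut <- dim(w)[3]
  fw <- fmaps
  dim(fw) <- c(n, n * dIn)
  wmat <- w
  dim(wmat) <- c(n * dIn, dOut)
  fw %*% wmat # E[i,b] = sum_a sum_k f[i,k,a] w[k,a,b]
}

#' Edge-to-node aggregation layer
#'
#' Aggregates each node's incident edge features into a node embedding:
#' `e[i,b] = lReLU( sum_a sum_k w[k,a,b] f[i,k,a] )`.
#'
#' @param fmaps Edge-feature tensor, `n x n x d_in`.
#' @param w Kernels, `n x d_in x d_out` array.
#' @param slope Leaky ReLU slope.
#' @return Node-feature matrix, `n x d_out`.
#' @export
e2nForward <- function(fmaps, w, slope = 1 / 3) {
  if (!identical(dim(fmaps)[c(1, 3)], dim(w)[c(1, 2)]))
    stop("edge-to-node kernel shape does not match the input tensor",
      call. = FALSE)
  leakyRelu(e2nPre(fmaps, w), slope)
}

## raw adjacency logits R for each embedding mode
embedLogits <- function(g, fL, params, mode) {
  n <- nrow(g)
  if (mode == "identity") return(g)
  if (mode == "averaging") {
    d <- dim(fL)[3]
    R <- matrix(0, n, n)
    for (a in seq_len(d)) R <- R + fL[, , a]
    return(R / d)
  }
  if (mode == "e2e") {
    d <- dim(fL)[3]
    Rrow <- numeric(n)
    Ccol <- numeric(n)
    for (a in seq_len(d)) {
      Rrow <- Rrow + fL[, , a] %*% params$embedR[, a]
      Ccol <- Ccol + t(fL[, , a]) %*% params$embedC[, a]
    }
    return(matrix(Rrow, n, n) + matrix(Ccol, n, n, byrow = TRUE))
  }
  stop("unknown adjacency mode '", mode, "'", call. = FALSE)
}

#' Embed the binary adjacency used by the pooling network
#'
#' Derives adjacency logits `R` from the input connectivity (`identity`
#' mode), a learned edge-to-edge map over the last extractor layer (`e2e`
#' mode), or the mean of the last layer's hidden edge features
#' (`averaging`). An edge is present when `sigmoid(R) >= 0.5`, i.e.
#' `R >= 0` (ties count as present); the result is symmetrized by logical
#' OR, as the GCN propagation expects a symmetric adjacency.
#'
#' @param g Input connectivity matrix (`n x n`).
#' @param fL Final edge-to-edge feature tensor (`n x n x d`), required for
#'   `e2e` and `averaging` modes.
#' @param params Model parameter list (uses `embedR`/`embedC` in `e2e` mode).
#' @param mode One of `"identity"`, `"e2e"`, `"averaging"`.
#' @return List with binary 0/1 adjacency `A` and the logits `R`.
#' @export
embedAdjacency <- function(g, fL = NULL, params = NULL,
                           mode = c("identity", "e2e", "averaging")) {
  mode <- match.arg(mode)
  if (mode != "identity" && is.null(fL))
    stop("fL tensor required for mode '", mode, "'", call. = FALSE)
  R <- embedLogits(g, fL, params, mode)
  A <- 1 * ((R >= 0) | (t(R) >= 0))
  list(A = A, R = R)
}

## symmetric degree-normalized self-loop propagation matrix
normAdj <- function(A) {
  At <- A + diag(nrow(A))
  s <- 1 / sqrt(rowSums(At))
  At * outer(s, s)
}

#' Graph convolution propagation
#'
#' Computes `D^{-1/2} (A + I) D^{-1/2} X W` where `D` is the diagonal degree
#' matrix of the self-loop-augmented adjacency.
#'
#' @param X Node-feature matrix (rows = nodes).
#' @param A Square 0/1 adjacency.
#' @param W Weight matrix.
#' @return Propagated feature matrix.
#' @export
gcnForward <- function(X, A, W) {
  X <- as.matrix(X)
  if (nrow(X) != nrow(A)) stop("X rows must match adjacency dim", call. = FALSE)
  normAdj(A) %*% X %*% W
}

#' Self-attention node scores
#'
#' Two stacked graph convolutions with a leaky ReLU between and a sigmoid on
#' top: `S = sigmoid(GCN(lReLU(GCN(X, A; W0)), A; W1))`, giving one score in
#' (0, 1) per node.
#'
#' @param X Node features (`n_l x m`).
#' @param A Binary adjacency (`n_l x n_l`).
#' @param W0 First GCN weight (`m x p`).
#' @param W1 Second GCN weight (`p x 1`).
#' @param slope Leaky ReLU slope.
#' @return Numeric vector of node scores in (0, 1).
#' @export
attentionScores <- function(X, A, W0, W1, slope = 1 / 3) {
  H1 <- gcnForward(X, A, W0)
  S <- gcnForward(leakyRelu(H1, slope), A, W1)
  as.vector(sigmoid(S))
}

#' Top-k pooling with residual attention gating
#'
#' Keeps the `ceiling(ratio * n_l)` nodes of highest score (ties broken by
#' lowest original index), subsets features, scores and adjacency to the
#' survivors (preserving original node order), and gates the surviving
#' features as `X_kept * (1 + S_kept)` row-wise — the element-wise attention
#' product plus the identity (residual) mapping.
#'
#' @param X Node features (`n_l x m`).
#' @param A Binary adjacency.
#' @param S Node scores (length `n_l`).
#' @param ratio Keep fraction in (0, 1].
#' @param nodeIds Original node indices carried through pooling.
#' @return List with pooled `X`, `A`, `S`, and surviving `nodeIds`.
#' @export
topkPool <- function(X, A, S, ratio = 0.5, nodeIds = seq_along(S)) {
  if (ratio <= 0 || ratio > 1) stop("ratio must be in (0, 1]", call. = FALSE)
  nl <- length(S)
  k <- ceiling(ratio * nl)
  ord <- order(-S, seq_len(nl))
  keep <- sort(ord[seq_len(k)])
  Xk <- X[keep, , drop = FALSE]
  Sk <- S[keep]
  list(
    X = Xk * (1 + Sk), A = A[keep, keep, drop = FALSE], S = Sk,
    nodeIds = nodeIds[keep], keep = keep
  )
}

#' Hierarchical readout
#'
#' Concatenates the per-layer mean and maximum over nodes of each pooled
#' feature matrix and sums the concatenations across layers, producing a
#' fixed-length vector of twice the feature width.
#'
#' @param layerStates List of pooled node-feature matrices (shared width).
#' @return Numeric vector of length `2 m`.
#' @export
readoutGraph <- function(layerStates) {
  if (!length(layerStates)) stop("need at least one layer state", call. = FALSE)
  zs <- lapply(layerStates, function(X) {
    X <- as.matrix(X)
    if (nrow(X) == 0) stop("empty node set in readout", call. = FALSE)
    c(colMeans(X), apply(X, 2, max))
  })
  Reduce(`+`, zs)
}

#' Full forward pass of the severity-prediction network
#'
#' Composes the stacked edge-to-edge layers, the edge-to-node aggregation,
#' the adjacency embedding, the self-attention pooling layers, the
#' hierarchical readout and the dense prediction head into a single scalar
#' severity prediction.
#'
#' @param g Preprocessed (thresholded, standardized) connectivity matrix.
#' @param params Parameter list from [initParams()].
#' @param config A [ModelConfig-class].
#' @param intermediates If `TRUE`, also return every intermediate quantity
#'   (edge tensors, node embeddings, adjacency, scores, pooled states,
#'   readout) for interpretation and gradient computation.
#' @return List with `prediction` (scalar) and, if requested, `state`.
#' @export
modelForward <- function(g, params, config, intermediates = FALSE) {
  g <- as.matrix(g)
  n <- config@nROIs
  stopifnot(nrow(g) == n, ncol(g) == n)
  slope <- config@leakySlope

  fmaps <- vector("list", config@nE2ELayers + 1L)
  pres <- vector("list", config@nE2ELayers)
  fmaps[[1]] <- array(g, c(n, n, 1L))
  for (l in seq_len(config@nE2ELayers)) {
    pres[[l]] <- e2ePre(fmaps[[l]], params$e2e[[l]]$r, params$e2e[[l]]$c)
    fmaps[[l + 1L]] <- leakyRelu(pres[[l]], slope)
  }
  fL <- fmaps[[config@nE2ELayers + 1L]]

  Epre <- e2nPre(fL, params$e2n)
  E <- leakyRelu(Epre, slope)

  emb <- embedAdjacency(g, fL, params, config@adjacencyMode)

  X <- E
  A <- emb$A
  nodeIds <- seq_len(n)
  layers <- vector("list", config@nAttLayers)
  for (l in seq_len(config@nAttLayers)) {
    P <- normAdj(A)
    Q0 <- P %*% X
    H1 <- Q0 %*% params$att[[l]]$W0
    H1a <- leakyRelu(H1, slope)
    Q1 <- P %*% H1a
    H2 <- Q1 %*% params$att[[l]]$W1
    S <- as.vector(sigmoid(H2))
    pool <- topkPool(X, A, S, config@poolRatio, nodeIds)
    layers[[l]] <- list(
      X = X, A = A, P = P, Q0 = Q0, H1 = H1, H1a = H1a, Q1 = Q1, S = S,
      keep = pool$keep, Xk = X[pool$keep, , drop = FALSE], Sk = pool$S,
      Xn = pool$X, nodeIds = nodeIds
    )
    X <- pool$X
    A <- pool$A
    nodeIds <- pool$nodeIds
  }

  z <- readoutGraph(lapply(layers, `[[`, "Xn"))

  nh <- length(params$mlp$W)
  acts <- vector("list", nh + 1L)
  mpre <- vector("list", nh)
  acts[[1]] <- z
  for (i in seq_len(nh)) {
    mpre[[i]] <- as.vector(crossprod(params$mlp$W[[i]], acts[[i]])) +
      params$mlp$b[[i]]
    acts[[i + 1L]] <- if (i < nh) leakyRelu(mpre[[i]], slope) else mpre[[i]]
  }
  pred <- acts[[nh + 1L]]

  out <- list(prediction = as.numeric(pred))
  if (intermediates) {
    out$state <- list(
      g = g, fmaps = fmaps, pres = pres, fL = fL, Epre = Epre, E = E,
      R = emb$R, A1 = emb$A, layers = layers, z = z, mpre = mpre, acts = acts,
      nodeIds = nodeIds
    )
  }
  out
}
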