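## gradient of the normalized propagation matrix w.r.t. the adjacency.
## P = s s^T * (A + I), s = rowSums(A + I)^{-1/2}; given dL/dP returns dL/dA
gradNormAdj <- function(dP, A) {
  At <- A + diag(nrow(A))
  deg <- rowSums(At)
  s <- 1 / sqrt(deg)
  P <- At * outer(s, s)
  dd <- -(rowSums(dP * P) + colSums(dP * P)) / (2 * deg)
  outer(s, s) * dP + matrix(dd, nrow(A), ncol(A))
}

#' Backward pass: gradients of the prediction
#'
#' Analytically backpropagates a scalar gradient `dy` through the full
#' network, returning gradients for every parameter and for the input
#' connectivity matrix. The hard 0.5 adjacency threshold is piecewise
#' constant; `adjGrad = "detach"` (the exact local gradient, used for
#' saliency and finite-difference checks) treats the binary adjacency as a
#' constant, while `adjGrad = "straight"` (the training default) substitutes
#' the sigmoid of the adjacency logits for the threshold in the backward
#' pass so the embedding path receives gradient.
#'
#' @param fw Result of `modelForward(..., intermediates = TRUE)`.
#' @param params Parameter list used for the forward pass.
#' @param config A [ModelConfig-class].
#' @param dy Upstream scalar gradient (default 1).
#' @param adjGrad `"detach"` or `"straight"`.
#' @return List with `grads` (same structure as `params`) and `dInput`
#'   (`n x n` gradient w.r.t. the input matrix).
#' @keywords internal
modelBackward <- function(fw, params, config, dy = 1,
                          adjGrad = c("detach", "straight")) {
  adjGrad <- match.arg(adjGrad)
  st <- fw$state
  slope <- config@leakySlope
  n <- config@nROIs
  grads <- zeroLike(params)

  ## ---- prediction head ----
  nh <- length(params$mlp$W)
  da <- dy
  for (i in nh:1) {
    dpre <- if (i < nh) da * lreluGrad(st$mpre[[i]], slope) else da
    grads$mlp$W[[i]] <- outer(st$acts[[i]], dpre)
    grads$mlp$b[[i]] <- dpre
    da <- as.vector(params$mlp$W[[i]] %*% dpre)
  }
  dz <- da

  ## ---- readout: identical dz feeds every attention layer ----
  m <- config@nMaps
  dzMean <- dz[seq_len(m)]
  dzMax <- dz[m + seq_len(m)]
  readoutGrad <- function(Xn) {
    k <- nrow(Xn)
    dXn <- matrix(dzMean / k, k, m, byrow = TRUE)
    amax <- apply(Xn, 2, which.max)
    dXn[cbind(amax, seq_len(m))] <- dXn[cbind(amax, seq_len(m))] + dzMax
    dXn
  }

  ## ---- attention-pooling layers, last to first ----
  L <- config@nAttLayers
  dXdown <- NULL # gradient w.r.t. the input X of the layer above
  dAdown <- NULL # gradient w.r.t. the input A of the layer above
  for (l in L:1) {
    lay <- st$layers[[l]]
    nl <- length(lay$S)
    dXn <- readoutGrad(lay$Xn)
    if (!is.null(dXdown)) dXn <- dXn + dXdown
    dXk <- dXn * (1 + lay$Sk)
    dSk <- rowSums(dXn * lay$Xk)
    dX <- matrix(0, nl, m)
    dX[lay$keep, ] <- dXk
    dS <- numeric(nl)
    dS[lay$keep] <- dSk
    dA <- matrix(0, nl, nl)
    if (!is.null(dAdown)) dA[lay$keep, lay$keep] <- dAdown

    ## score stack: S = sigmoid(P lrelu(P X W0) W1)
    dH2 <- matrix(dS * lay$S * (1 - lay$S), nl, 1)
    grads$att[[l]]$W1 <- crossprod(lay$Q1, dH2)
    dH1a <- (lay$P %*% dH2) %*% t(params$att[[l]]$W1)
    dH1 <- dH1a * lreluGrad(lay$H1, slope)
    grads$att[[l]]$W0 <- crossprod(lay$Q0, dH1)
    dX <- dX + (lay$P %*% dH1) %*% t(params$att[[l]]$W0)

    if (adjGrad == "straight") {
      dP <- dH2 %*% t(lay$H1a %*% params$att[[l]]$W1) +
        dH1 %*% t(lay$X %*% params$att[[l]]$W0)
      dA <- dA + gradNormAdj(dP, lay$A)
    }
    dXdown <- dX
    dAdown <- dA
  }
  dE <- dXdown
  dA1 <- dAdown

  ## ---- adjacency embedding (straight-through only) ----
  dG <- matrix(0, n, n)
  dfL <- array(0, dim(st$fL))
  if (adjGrad == "straight") {
    sig <- sigmoid(st$R)
    dR <- ((dA1 + t(dA1)) / 2) * sig * (1 - sig)
    mode <- config@adjacencyMode
    if (mode == "identity") {
      dG <- dG + dR
    } else if (mode == "averaging") {
      d <- dim(st$fL)[3]
      for (a in seq_len(d)) dfL[, , a] <- dfL[, , a] + dR / d
    } else {
      u <- rowSums(dR)
      v <- colSums(dR)
      d <- dim(st$fL)[3]
      grads$embedR <- matrix(0, n, d)
      grads$embedC <- matrix(0, n, d)
      for (a in seq_len(d)) {
        fa <- st$fL[, , a]
        grads$embedR[, a] <- crossprod(fa, u)
        grads$embedC[, a] <- fa %*% v
        dfL[, , a] <- dfL[, , a] + outer(u, params$embedR[, a]) +
          outer(params$embedC[, a], v)
      }
    }
  }

  ## ---- edge-to-node layer (block-matrix form, see e2ePre) ----
  dEpre <- dE * lreluGrad(st$Epre, slope)
  dIn <- dim(st$fL)[3]
  dOut <- dim(params$e2n)[3]
  fLw <- st$fL
  dim(fLw) <- c(n, n * dIn)
  dw <- crossprod(fLw, dEpre) # (n dIn) x dOut
  dim(dw) <- c(n, dIn, dOut)
  grads$e2n <- dw
  wmat <- params$e2n
  dim(wmat) <- c(n * dIn, dOut)
  dfLw <- dEpre %*% t(wmat) # n x (n dIn)
  dim(dfL) <- c(n, n * dIn)
  dfL <- dfL + dfLw
  dim(dfL) <- c(n, n, dIn)

  ## ---- edge-to-edge layers, last to first ----
  dOutMaps <- dfL
  for (l in config@nE2ELayers:1) {
    dPre <- dOutMaps * lreluGrad(st$pres[[l]], slope)
    dO <- dim(dPre)[3]
    dPw <- dPre
    dim(dPw) <- c(n, n * dO)
    ## U[,b] = row sums of map b; V[,b] = column sums of map b
    U <- dPw %*% kronecker(diag(dO), rep(1, n))
    V <- colSums(dPw)
    dim(V) <- c(n, dO)
    fw <- st$fmaps[[l]]
    dI <- dim(fw)[3]
    dim(fw) <- c(n, n * dI)
    dr <- crossprod(fw, U) # dr[(a-1)n+k, b] = sum_i f[i,k,a] U[i,b]
    dim(dr) <- c(n, dI, dO)
    grads$e2e[[l]]$r <- dr
    rmat <- params$e2e[[l]]$r
    dim(rmat) <- c(n * dI, dO)
    dInW <- U %*% t(rmat) # row-kernel path back to all input maps
    for (a in seq_len(dI)) {
      cols <- ((a - 1L) * n + 1L):(a * n)
      fa <- fw[, cols, drop = FALSE]
      grads$e2e[[l]]$c[, a, ] <- fa %*% V
      dInW[, cols] <- dInW[, cols] +
        matrix(params$e2e[[l]]$c[, a, ], n, dO) %*% t(V)
    }
    dim(dInW) <- c(n, n, dI)
    dOutMaps <- dInW
  }
  dG <- dG + dOutMaps[, , 1]

  list(grads = grads, dInput = dG)
}
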