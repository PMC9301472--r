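# Independent brute-force oracles used to pin down every layer and measure.
# Deliberately naive (nested loops, full sorts, power series) and kept free
# of any package internals beyond exported activation conventions.

lreluRef <- function(x, slope = 1 / 3) ifelse(x >= 0, x, slope * x)

# per-pair demeaned-quotient Pearson formula
pearsonOracle <- function(ts) {
  n <- ncol(ts)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ti <- ts[, i] - mean(ts[, i])
      tj <- ts[, j] - mean(ts[, j])
      out[i, j] <- sum(ti * tj) / sqrt(sum(ti * ti) * sum(tj * tj))
    }
  }
  out
}

# quadruple-nested-loop edge-to-edge layer
e2eOracle <- function(f, r, c, slope = 1 / 3) {
  n <- dim(f)[1]
  dIn <- dim(f)[3]
  dOut <- dim(r)[3]
  out <- array(0, c(n, n, dOut))
  for (b in seq_len(dOut)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        acc <- 0
        for (a in seq_len(dIn)) {
          for (k in seq_len(n)) {
            acc <- acc + r[k, a, b] * f[i, k, a] + c[k, a, b] * f[k, j, a]
          }
        }
        out[i, j, b] <- lreluRef(acc, slope)
      }
    }
  }
  out
}

# triple-loop edge-to-node layer
e2nOracle <- function(f, w, slope = 1 / 3) {
  n <- dim(f)[1]
  dIn <- dim(f)[3]
  dOut <- dim(w)[3]
  out <- matrix(0, n, dOut)
  for (b in seq_len(dOut)) {
    for (i in seq_len(n)) {
      acc <- 0
      for (a in seq_len(dIn)) {
        for (k in seq_len(n)) acc <- acc + w[k, a, b] * f[i, k, a]
      }
      out[i, b] <- lreluRef(acc, slope)
    }
  }
  out
}

# dense matrix-product GCN oracle
gcnOracle <- function(X, A, W) {
  n <- nrow(A)
  At <- A + diag(n)
  D <- diag(rowSums(At))
  Dm <- diag(1 / sqrt(diag(D)))
  Dm %*% At %*% Dm %*% as.matrix(X) %*% W
}

attentionOracle <- function(X, A, W0, W1, slope = 1 / 3) {
  H <- gcnOracle(X, A, W0)
  H <- apply(H, c(1, 2), lreluRef, slope = slope)
  as.vector(1 / (1 + exp(-gcnOracle(H, A, W1))))
}

readoutOracle <- function(states) {
  m <- ncol(states[[1]])
  z <- numeric(2 * m)
  for (X in states) {
    for (c in seq_len(m)) {
      z[c] <- z[c] + mean(X[, c])
      z[m + c] <- z[m + c] + max(X[, c])
    }
  }
  z
}

# straight-line monolithic forward reimplementation (identity adjacency
# handled via threshold on g; e2e/averaging via the published formulas)
modelForwardOracle <- function(g, params, config) {
  slope <- config@leakySlope
  n <- config@nROIs
  f <- array(g, c(n, n, 1))
  for (l in seq_len(config@nE2ELayers)) {
    f <- e2eOracle(f, params$e2e[[l]]$r, params$e2e[[l]]$c, slope)
  }
  E <- e2nOracle(f, params$e2n, slope)
  R <- switch(config@adjacencyMode,
    identity = g,
    averaging = apply(f, c(1, 2), mean),
    e2e = {
      Rm <- matrix(0, n, n)
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          for (a in seq_len(dim(f)[3])) {
            Rm[i, j] <- Rm[i, j] +
              sum(params$embedR[, a] * f[i, , a]) +
              sum(params$embedC[, a] * f[, j, a])
          }
        }
      }
      Rm
    }
  )
  sig <- 1 / (1 + exp(-R))
  A <- 1 * ((sig >= 0.5) | (t(sig) >= 0.5))
  X <- E
  states <- list()
  for (l in seq_len(config@nAttLayers)) {
    S <- attentionOracle(X, A, params$att[[l]]$W0, params$att[[l]]$W1, slope)
    k <- ceiling(config@poolRatio * length(S))
    keep <- sort(order(-S, seq_along(S))[seq_len(k)])
    X <- X[keep, , drop = FALSE] * (1 + S[keep])
    A <- A[keep, keep, drop = FALSE]
    states[[l]] <- X
  }
  z <- readoutOracle(states)
  a <- z
  nh <- length(params$mlp$W)
  for (i in seq_len(nh)) {
    pre <- as.vector(t(params$mlp$W[[i]]) %*% a) + params$mlp$b[[i]]
    a <- if (i < nh) lreluRef(pre, slope) else pre
  }
  as.numeric(a)
}

# full-sort proportional-threshold oracle (returns kept upper-tri logical)
thresholdOracle <- function(v, sparsity) {
  n <- nrow(v)
  ut <- which(upper.tri(v), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  vals <- v[ut]
  m <- floor(sparsity * n * (n - 1) / 2)
  ord <- order(-abs(vals), ut[, 1], ut[, 2])
  keep <- rep(FALSE, length(vals))
  keep[ord[seq_len(m)]] <- TRUE
  keep & abs(vals) > 0
}

# all-geodesic betweenness by path counting (dense DP, n <= 8)
betweennessOracle <- function(B) {
  n <- nrow(B)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  # BFS distances
  for (s in seq_len(n)) {
    frontier <- s
    dist <- 0
    while (length(frontier)) {
      dist <- dist + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(B[v, ] > 0)) {
          if (D[s, w] > dist) {
            D[s, w] <- dist
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  # geodesic counts between every pair
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(D[s, ])
    for (v in ord) {
      if (v == s || !is.finite(D[s, v])) next
      preds <- which(B[, v] > 0 & D[s, ] == D[s, v] - 1)
      sigma[s, v] <- sum(sigma[s, preds])
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(D[s, t])) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  btw
}

# iterative-pruning k-core oracle
kcoreOracle <- function(B) {
  n <- nrow(B)
  core <- numeric(n)
  for (k in seq_len(n)) {
    alive <- rep(TRUE, n)
    repeat {
      deg <- rowSums(B[, alive, drop = FALSE]) * alive
      drop <- alive & deg < k
      if (!any(drop)) break
      alive[drop] <- FALSE
    }
    core[alive] <- k
    if (!any(alive)) break
  }
  core
}

# truncated power-series subgraph centrality
subgraphOracle <- function(B, terms = 30) {
  n <- nrow(B)
  acc <- diag(n)
  term <- diag(n)
  for (m in seq_len(terms)) {
    term <- term %*% B / m
    acc <- acc + term
  }
  diag(acc)
}

# sqrt of largest eigenvalue of S11^-1 S12 S22^-1 S21
ccaEigenOracle <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  S11 <- crossprod(Xc) / (nrow(X) - 1)
  S22 <- crossprod(Yc) / (nrow(Y) - 1)
  S12 <- crossprod(Xc, Yc) / (nrow(X) - 1)
  M <- solve(S11) %*% S12 %*% solve(S22) %*% t(S12)
  sqrt(max(Re(eigen(M)$values)))
}

# small random symmetric test matrix with zero diagonal
randomSymmetric <- function(n, sd = 1) {
  m <- matrix(rnorm(n * n, sd = sd), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# random undirected 0/1 graph
randomGraph <- function(n, p = 0.4) {
  m <- matrix(rbinom(n * n, 1, p), n)
  m[lower.tri(m, diag = TRUE)] <- 0
  m + t(m)
}

# tiny raw cohort for pipeline tests
tinyCohort <- function(N = 12, n = 10, seed = 42) {
  set.seed(seed)
  mats <- lapply(seq_len(N), function(k) randomSymmetric(n))
  ph <- data.frame(
    subject_id = sprintf("s%02d", seq_len(N)),
    site = rep(c("A", "B"), length.out = N),
    age = runif(N, 8, 25), sex = rbinom(N, 1, 0.5),
    score = rnorm(N, 6, 2)
  )
  ConnectivityCohort(mats, ph, targetName = "score")
}
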