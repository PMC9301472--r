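test_that("leaky ReLU follows the slope-1/3 convention", {
  expect_equal(leakyRelu(2, 1 / 3), 2)
  expect_equal(leakyRelu(-3, 1 / 3), -1)
  expect_equal(leakyRelu(0, 1 / 3), 0)
  expect_equal(leakyRelu(c(-6, 6), 0.2), c(-1.2, 6))
})

test_that("edge-to-edge layer matches hand sums and the nested-loop oracle", {
  # all-ones kernels on the 2-node swap matrix: every pre-activation is 2
  f <- array(c(0, 1, 1, 0), c(2, 2, 1))
  r <- array(1, c(2, 1, 1))
  expect_equal(e2eForward(f, r, r), array(2, c(2, 2, 1)))
  # zero input stays zero
  expect_equal(e2eForward(array(0, c(3, 3, 2)), array(1, c(3, 2, 2)),
    array(1, c(3, 2, 2))), array(0, c(3, 3, 2)))
  # seeded instances against the quadruple loop
  set.seed(40)
  for (rep in 1:5) {
    n <- sample(3:6, 1); dIn <- sample(1:3, 1); dOut <- sample(1:3, 1)
    f <- array(rnorm(n * n * dIn), c(n, n, dIn))
    r <- array(rnorm(n * dIn * dOut), c(n, dIn, dOut))
    c <- array(rnorm(n * dIn * dOut), c(n, dIn, dOut))
    expect_lt(max(abs(e2eForward(f, r, c) - e2eOracle(f, r, c))), 1e-10)
  }
  expect_error(e2eForward(f, array(1, c(2, 2, 2)), array(1, c(2, 2, 2))),
    "shape")
})

test_that("edge-to-node layer matches hand sums and the nested-loop oracle", {
  f <- array(c(0, 1, 1, 0), c(2, 2, 1))
  expect_equal(e2nForward(f, array(1, c(2, 1, 1))), matrix(1, 2, 1))
  expect_equal(e2nForward(f, array(0, c(2, 1, 2))), matrix(0, 2, 2))
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(3:6, 1); dIn <- sample(1:3, 1); dOut <- sample(1:3, 1)
    f <- array(rnorm(n * n * dIn), c(n, n, dIn))
    w <- array(rnorm(n * dIn * dOut), c(n, dIn, dOut))
    expect_lt(max(abs(e2nForward(f, w) - e2nOracle(f, w))), 1e-10)
  }
})

test_that("adjacency embedding thresholds at sigmoid(R) >= 0.5", {
  g <- matrix(c(0, -0.2, -0.2, 0.3, 0, 0.3, 0.3, 0.3, 0), 3, 3)
  g <- (g + t(g)) / 2
  emb <- embedAdjacency(g, mode = "identity")
  expect_equal(emb$A, 1 * (g >= 0)) # tie at 0 counts as an edge
  # averaging of identical maps reproduces the map
  f <- array(rep(g, 2), c(3, 3, 2))
  emb2 <- embedAdjacency(g, f, mode = "averaging")
  expect_equal(emb2$R, g)
  # zero e2e kernel: R = 0 everywhere -> complete graph
  p <- list(embedR = matrix(0, 3, 2), embedC = matrix(0, 3, 2))
  emb3 <- embedAdjacency(g, f, p, mode = "e2e")
  expect_true(all(emb3$A == 1))
  expect_error(embedAdjacency(g, mode = "e2e"), "fL")
})

test_that("identity adjacency of a standardized matrix flags nonnegatives", {
  set.seed(42)
  cm <- standardizeMatrix(proportionalThreshold(
    ConnectivityMatrix(randomSymmetric(12)), 0.3))
  g <- connValues(cm)
  expect_equal(embedAdjacency(g, mode = "identity")$A,
    1 * ((g >= 0) | (t(g) >= 0)))
})

test_that("graph convolution matches the dense-product oracle", {
  # isolated nodes: self-loop only, output reduces to X W
  X <- matrix(rnorm(6), 2, 3)
  W <- matrix(rnorm(6), 3, 2)
  expect_equal(gcnForward(X, matrix(0, 2, 2), W), X %*% W)
  # 3-node path graph
  set.seed(43)
  A <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  X3 <- matrix(rnorm(9), 3, 3)
  W3 <- matrix(rnorm(6), 3, 2)
  expect_lt(max(abs(gcnForward(X3, A, W3) - gcnOracle(X3, A, W3))), 1e-12)
})

test_that("attention scores compose two GCNs inside a sigmoid", {
  set.seed(44)
  n <- 6; m <- 4; p <- 2
  A <- randomGraph(n)
  X <- matrix(rnorm(n * m), n)
  W0 <- matrix(rnorm(m * p), m)
  W1 <- matrix(rnorm(p), p, 1)
  S <- attentionScores(X, A, W0, W1)
  expect_lt(max(abs(S - attentionOracle(X, A, W0, W1))), 1e-12)
  expect_true(all(S > 0 & S < 1))
  # zero weights: every score is sigmoid(0) = 0.5
  expect_equal(attentionScores(X, A, 0 * W0, 0 * W1), rep(0.5, n))
})

test_that("top-k pooling keeps ceil(ratio n) nodes with residual gating", {
  set.seed(45)
  X <- matrix(rnorm(8), 4, 2)
  A <- randomGraph(4)
  S <- c(0.9, 0.2, 0.6, 0.4)
  out <- topkPool(X, A, S, ratio = 0.5)
  expect_identical(out$nodeIds, c(1L, 3L)) # top-2 by full sort
  expect_equal(out$X, X[c(1, 3), ] * (1 + S[c(1, 3)]))
  expect_equal(out$A, A[c(1, 3), c(1, 3)])
  # equal scores: ties broken by lowest original index
  out2 <- topkPool(X, A, rep(0.7, 4), ratio = 0.5)
  expect_identical(out2$nodeIds, c(1L, 2L))
  expect_equal(out2$X, 1.7 * X[1:2, ])
  expect_error(topkPool(X, A, S, ratio = 0), "ratio")
})

test_that("readout concatenates mean/max per layer and sums layers", {
  # singleton node: mean = max = the feature vector
  x <- matrix(c(1.5, -2), 1, 2)
  expect_equal(readoutGraph(list(x)), c(1.5, -2, 1.5, -2))
  set.seed(46)
  states <- list(matrix(rnorm(12), 4, 3), matrix(rnorm(6), 2, 3))
  z <- readoutGraph(states)
  expect_identical(length(z), 6L) # 2 * feature width
  expect_equal(z, readoutOracle(states))
  # permutation invariance over nodes within a layer
  perm <- states
  perm[[1]] <- perm[[1]][c(3, 1, 4, 2), ]
  expect_equal(readoutGraph(perm), z)
})

test_that("full forward pass matches a monolithic straight-line oracle", {
  set.seed(47)
  for (mode in c("identity", "e2e", "averaging")) {
    cfg <- modelConfig(nROIs = 8, nMaps = 2, mlpSizes = c(6L, 4L),
      adjacencyMode = mode)
    for (rep in 1:4) {
      p <- initParams(cfg, seed = rep * 13)
      g <- randomSymmetric(8)
      got <- modelForward(g, p, cfg)$prediction
      expect_lt(abs(got - modelForwardOracle(g, p, cfg)), 1e-8)
    }
  }
})

test_that("zero-weight network predicts the (zero) final bias", {
  cfg <- modelConfig(nROIs = 6, nMaps = 2, mlpSizes = c(4L, 3L))
  p <- initParams(cfg, seed = 1)
  p <- severityNet:::mapParams1(p, function(x) x * 0)
  set.seed(48)
  for (rep in 1:3)
    expect_equal(modelForward(randomSymmetric(6), p, cfg)$prediction, 0)
})

test_that("node permutation with matching kernel permutation is equivariant", {
  set.seed(49)
  cfg <- modelConfig(nROIs = 7, nMaps = 2, mlpSizes = c(5L, 3L))
  p <- initParams(cfg, seed = 3)
  g <- randomSymmetric(7)
  perm <- sample(7)
  gP <- g[perm, perm]
  pP <- p
  for (l in 1:2) {
    pP$e2e[[l]]$r <- p$e2e[[l]]$r[perm, , , drop = FALSE]
    pP$e2e[[l]]$c <- p$e2e[[l]]$c[perm, , , drop = FALSE]
  }
  pP$e2n <- p$e2n[perm, , , drop = FALSE]
  expect_equal(modelForward(gP, pP, cfg)$prediction,
    modelForward(g, p, cfg)$prediction,
    tolerance = 1e-6)
})

test_that("pooled node count after two half-ratio layers is ceil(ceil(n/2)/2)", {
  set.seed(50)
  for (n in c(5, 8, 11, 16)) {
    cfg <- modelConfig(nROIs = n, nMaps = 2, mlpSizes = c(4L, 3L))
    p <- initParams(cfg, seed = n)
    fw <- modelForward(randomSymmetric(n), p, cfg, intermediates = TRUE)
    expect_identical(length(fw$state$nodeIds),
      as.integer(ceiling(ceiling(n / 2) / 2)))
    for (st in fw$state$layers) expect_true(all(st$S > 0 & st$S < 1))
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(51)
  n <- 8
  for (mode in c("identity", "e2e", "averaging")) {
    cfg <- modelConfig(nROIs = n, nMaps = 2, mlpSizes = c(6L, 4L),
      adjacencyMode = mode)
    p <- initParams(cfg, seed = 9)
    g <- randomSymmetric(n)
    fw <- modelForward(g, p, cfg, intermediates = TRUE)
    bw <- severityNet:::modelBackward(fw, p, cfg, dy = 1, adjGrad = "detach")
    v <- severityNet:::paramsToVector(p)
    gv <- severityNet:::paramsToVector(bw$grads)
    h <- 1e-4
    idx <- sort(sample(length(v), 40))
    for (i in idx) {
      vp <- v; vp[i] <- vp[i] + h
      vm <- v; vm[i] <- vm[i] - h
      fd <- (modelForward(g, severityNet:::vectorToParams(vp, p), cfg)$prediction -
        modelForward(g, severityNet:::vectorToParams(vm, p), cfg)$prediction) / (2 * h)
      expect_lt(abs(fd - gv[i]) / max(abs(fd) + abs(gv[i]), 1e-6), 1e-4)
    }
  }
})

test_that("compiled forward/backward core agrees with the R reference", {
  set.seed(52)
  for (mode in c("identity", "e2e", "averaging")) {
    cfg <- modelConfig(nROIs = 7, nMaps = 3, mlpSizes = c(5L, 4L),
      adjacencyMode = mode)
    cl <- severityNet:::cfgList(cfg)
    p <- initParams(cfg, seed = 21)
    g <- randomSymmetric(7)
    fw <- modelForward(g, p, cfg, intermediates = TRUE)
    expect_equal(severityNet:::cppPredict(g, p, cl), fw$prediction,
      tolerance = 1e-12)
    for (ag in c("detach", "straight")) {
      bw <- severityNet:::modelBackward(fw, p, cfg, dy = 1, adjGrad = ag)
      cb <- severityNet:::cppPredictionGrad(g, p, cl, ag == "straight")
      expect_lt(max(abs(severityNet:::paramsToVector(bw$grads) -
        severityNet:::paramsToVector(cb$grads))), 1e-10)
      expect_lt(max(abs(bw$dInput - cb$dInput)), 1e-10)
    }
  }
})

test_that("predictions stay finite on extreme finite inputs", {
  cfg <- modelConfig(nROIs = 6, nMaps = 2, mlpSizes = c(4L, 3L))
  p <- initParams(cfg, seed = 2)
  g <- randomSymmetric(6, sd = 100)
  expect_true(is.finite(modelForward(g, p, cfg)$prediction))
})
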