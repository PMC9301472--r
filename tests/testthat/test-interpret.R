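smallModel <- function(n = 10, d = 4, seed = 1, mode = "identity") {
  cfg <- modelConfig(nROIs = n, nMaps = d, mlpSizes = c(8L, 4L),
    adjacencyMode = mode)
  new("SeverityModel", config = cfg, params = initParams(cfg, seed),
    history = data.frame(), bestEpoch = 0L)
}

test_that("node embeddings are the edge-to-node output", {
  set.seed(80)
  mod <- smallModel()
  g <- randomSymmetric(10)
  emb <- extractNodeEmbeddings(g, mod)
  expect_identical(dim(emb), c(10L, 4L))
  # composition oracle: E2N applied to the E2E-propagated input
  f <- array(g, c(10, 10, 1))
  for (l in 1:2) f <- e2eOracle(f, mod@params$e2e[[l]]$r, mod@params$e2e[[l]]$c)
  expect_lt(max(abs(emb - e2nOracle(f, mod@params$e2n))), 1e-8)
  # zero weights give a zero embedding
  zp <- severityNet:::mapParams1(mod@params, function(x) x * 0)
  expect_true(all(extractNodeEmbeddings(g, zp, mod@config) == 0))
})

test_that("level 1 takes the best pairwise correlation per measure", {
  set.seed(81)
  n <- 50
  Xgm <- matrix(rnorm(n * 8), n)
  Xnf <- matrix(rnorm(n * 4), n)
  got <- level1PairwiseMax(Xgm, Xnf)
  ref <- apply(Xgm, 2, function(xm) {
    best <- -Inf
    for (j in seq_len(ncol(Xnf))) best <- max(best, cor(xm, Xnf[, j]))
    best
  })
  expect_equal(got, ref, ignore_attr = TRUE)
  # a measure planted among the features correlates perfectly
  Xnf2 <- cbind(Xnf, Xgm[, 3])
  expect_equal(level1PairwiseMax(Xgm, Xnf2)[3], 1, ignore_attr = TRUE)
  # single feature column reduces to plain correlation
  expect_equal(level1PairwiseMax(Xgm[, 1, drop = FALSE],
    Xnf[, 1, drop = FALSE]), cor(Xgm[, 1], Xnf[, 1]), ignore_attr = TRUE)
})

test_that("level 2 equals the sqrt R-squared of the per-measure regression", {
  set.seed(82)
  n <- 60
  Xgm <- matrix(rnorm(n * 8), n)
  Xnf <- matrix(rnorm(n * 5), n)
  got <- level2PerMeasureCCA(Xgm, Xnf)
  for (i in 1:8) {
    fit <- lm(Xgm[, i] ~ Xnf)
    expect_lt(abs(got[i] - sqrt(summary(fit)$r.squared)), 1e-6)
  }
  # an exact linear combination is recovered with correlation 1
  Xgm2 <- Xgm
  Xgm2[, 1] <- Xnf %*% c(1, -2, 0.5, 3, -1)
  expect_equal(level2PerMeasureCCA(Xgm2, Xnf)[1], 1, tolerance = 1e-6,
    ignore_attr = TRUE)
})

test_that("level 3 is the first canonical correlation (SVD route)", {
  set.seed(83)
  n <- 70
  X <- matrix(rnorm(n * 6), n)
  Y <- matrix(rnorm(n * 4), n)
  got <- level3FullCCA(X, Y)
  expect_lt(abs(got$correlation - ccaEigenOracle(X, Y)), 1e-6)
  # identical domains give correlation 1
  expect_equal(level3FullCCA(X, X)$correlation, 1, tolerance = 1e-6)
  # p = q = 1 degenerates to |Pearson r|
  expect_equal(
    level3FullCCA(X[, 1, drop = FALSE], Y[, 1, drop = FALSE])$correlation,
    abs(cor(X[, 1], Y[, 1])), tolerance = 1e-6)
  # canonical variates realize the reported correlation
  expect_equal(as.numeric(abs(cor(X %*% got$wgm, Y %*% got$wnf))), got$correlation,
    tolerance = 1e-6)
})

test_that("the three levels nest: level1 <= level2 <= level3", {
  set.seed(84)
  for (rep in 1:100) {
    n <- sample(30:60, 1)
    Xgm <- matrix(rnorm(n * 5), n)
    Xnf <- matrix(rnorm(n * 3), n)
    l1 <- level1PairwiseMax(Xgm, Xnf)
    l2 <- level2PerMeasureCCA(Xgm, Xnf)
    l3 <- level3FullCCA(Xgm, Xnf)$correlation
    expect_true(all(l2 >= abs(l1) - 1e-9))
    expect_true(l3 >= max(l2) - 1e-9)
  }
})

test_that("CCA levels are invariant to affine rescaling of either domain", {
  set.seed(85)
  n <- 50
  Xgm <- matrix(rnorm(n * 4), n)
  Xnf <- matrix(rnorm(n * 3), n)
  scaleX <- sweep(Xgm, 2, c(2, 0.5, 10, 1), `*`) + 3
  scaleY <- sweep(Xnf, 2, c(0.1, 5, 2), `*`) - 1
  expect_equal(level2PerMeasureCCA(scaleX, scaleY),
    level2PerMeasureCCA(Xgm, Xnf), tolerance = 1e-6)
  expect_equal(level3FullCCA(scaleX, scaleY)$correlation,
    level3FullCCA(Xgm, Xnf)$correlation, tolerance = 1e-6)
})

test_that("recovered level-3 correlation decays with embedding noise", {
  set.seed(86)
  n <- 60
  Xgm <- matrix(rnorm(n * 5), n)
  mix <- matrix(rnorm(5 * 3), 5, 3)
  rs <- vapply(c(0.1, 1, 4, 16), function(sigma) {
    mean(replicate(8, {
      Xnf <- Xgm %*% mix + matrix(rnorm(n * 3, sd = sigma), n)
      level3FullCCA(Xgm, Xnf)$correlation
    }))
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("constant columns are skipped with a warning", {
  set.seed(87)
  Xgm <- matrix(rnorm(40 * 3), 40)
  Xnf <- cbind(matrix(rnorm(40 * 2), 40), 5)
  expect_warning(level1PairwiseMax(Xgm, Xnf), "constant")
  expect_error(level1PairwiseMax(Xgm, matrix(1, 40, 2)), "constant")
})

test_that("saliency is the symmetrized input gradient", {
  set.seed(88)
  mod <- smallModel(n = 8, d = 2, seed = 4)
  g <- randomSymmetric(8)
  sal <- saliencyMap(g, mod)
  expect_equal(sal, t(sal))
  # symmetric-pair finite differences: d/dh f(g + h (E_ij + E_ji)) = 2 sal_ij
  h <- 1e-5
  pairs <- which(upper.tri(diag(8)), arr.ind = TRUE)
  for (k in 1:10) {
    pr <- pairs[sample(nrow(pairs), 1), ]
    i <- pr[1]; j <- pr[2]
    gp <- g; gp[i, j] <- gp[i, j] + h; gp[j, i] <- gp[j, i] + h
    gm <- g; gm[i, j] <- gm[i, j] - h; gm[j, i] <- gm[j, i] - h
    fd <- (modelForward(gp, mod@params, mod@config)$prediction -
      modelForward(gm, mod@params, mod@config)$prediction) / (2 * h)
    expect_lt(abs(fd - 2 * sal[i, j]) / max(abs(fd), 1e-6), 1e-4)
  }
  # an input-independent model has zero saliency
  zp <- mod@params
  zp$e2e[[1]]$r <- 0 * zp$e2e[[1]]$r
  zp$e2e[[1]]$c <- 0 * zp$e2e[[1]]$c
  zmod <- new("SeverityModel", config = mod@config, params = zp,
    history = data.frame(), bestEpoch = 0L)
  expect_true(all(saliencyMap(g, zmod) == 0))
})

test_that("group saliency averages maps and reports the top edges", {
  set.seed(89)
  maps <- lapply(1:5, function(k) randomSymmetric(5))
  grp <- groupSaliency(maps, keepFraction = 0.1)
  ref <- (maps[[1]] + maps[[2]] + maps[[3]] + maps[[4]] + maps[[5]]) / 5
  expect_equal(grp$map, ref)
  expect_identical(nrow(grp$edges), 1L) # floor(0.1 * 10) = 1
  expect_equal(abs(grp$edges$pd_value),
    max(abs(ref[upper.tri(ref)])))
  # one subject: group map equals the subject map
  expect_equal(groupSaliency(maps[1])$map, maps[[1]])
  grpAll <- groupSaliency(maps, keepFraction = 1)
  expect_identical(nrow(grpAll$edges), 10L)
  expect_false(is.unsorted(rev(abs(grpAll$edges$pd_value))))
})

test_that("per-subject cohort CCA produces the three-level summary", {
  sim <- simulateCohort(simulationConfig(nSubjects = 6L, nROIs = 12L,
    supportSize = 6L, sparsity = 0.25, seed = 9))
  built <- buildCohort(sim$cohort, sparsity = 0.25)
  mod <- smallModel(n = 12, d = 4, seed = 2)
  res <- ccaNodeAnalysis(built, mod)
  expect_setequal(unique(res$perSubject$level),
    c("level1", "level2", "level3"))
  expect_identical(nrow(res$perSubject), 6L * 17L) # 8 + 8 + 1 per subject
  l3 <- res$summary[res$summary$level == "level3", ]
  expect_true(l3$mean >= 0 && l3$mean <= 1)
  # nesting holds per subject at the cohort level too
  for (id in unique(res$perSubject$subject_id)[1:3]) {
    sub <- res$perSubject[res$perSubject$subject_id == id, ]
    expect_gte(sub$value[sub$level == "level3"],
      max(sub$value[sub$level == "level2"], na.rm = TRUE) - 1e-9)
  }
})
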