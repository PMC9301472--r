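test_that("Pearson connectivity matches the per-pair demeaned formula", {
  set.seed(11)
  ts <- matrix(rnorm(20 * 4), 20, 4)
  cm <- pearsonConnectivity(ts)
  expect_s4_class(cm, "ConnectivityMatrix")
  expect_lt(max(abs(connValues(cm) - pearsonOracle(ts))), 1e-12)
  expect_true(all(abs(connValues(cm)) <= 1 + 1e-12))
  expect_equal(diag(connValues(cm)), rep(1, 4))
})

test_that("Pearson handles perfect correlation and anticorrelation", {
  ts <- cbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(2, 4, 6))
  v <- connValues(pearsonConnectivity(ts))
  expect_equal(v[1, 2], -1)
  expect_equal(v[1, 3], 1) # identical up to affine scaling
})

test_that("Pearson is invariant under affine rescaling of a series", {
  set.seed(12)
  ts <- matrix(rnorm(30 * 5), 30, 5)
  ts2 <- ts
  ts2[, 3] <- 2.5 * ts[, 3] + 7
  expect_equal(connValues(pearsonConnectivity(ts)),
    connValues(pearsonConnectivity(ts2)),
    tolerance = 1e-12)
})

test_that("Pearson rejects degenerate series naming the ROI", {
  ts <- cbind(x = rnorm(10), flatliner = rep(2, 10))
  expect_error(pearsonConnectivity(ts), "flatliner")
})

test_that("Tikhonov precision has closed forms", {
  # identity covariance: P = I / (1 + rho)
  expect_equal(tikhonovPrecision(diag(4), rho = 0.1), diag(4) / 1.1)
  # hand-inverted 2x2, det = 1.1^2 - 0.5^2 = 0.96
  C <- matrix(c(1, 0.5, 0.5, 1), 2)
  P <- tikhonovPrecision(C, rho = 0.1)
  expect_equal(P, matrix(c(1.1, -0.5, -0.5, 1.1), 2) / 0.96,
    tolerance = 1e-12)
  expect_equal(P[1, 1], 1.145833, tolerance = 1e-6)
  expect_equal(P[1, 2], -0.520833, tolerance = 1e-6)
  # rho = 0 reduces to the plain inverse
  expect_equal(tikhonovPrecision(C, rho = 0), solve(C), tolerance = 1e-12)
})

test_that("Tikhonov connectivity inverts C + rho I", {
  set.seed(13)
  ts <- matrix(rnorm(60 * 6), 60, 6)
  cm <- tikhonovConnectivity(ts, rho = 0.1)
  tc <- scale(ts, scale = FALSE)
  C <- crossprod(tc) / nrow(ts) # 1/T empirical covariance
  expect_lt(max(abs((C + 0.1 * diag(6)) %*% connValues(cm) - diag(6))), 1e-8)
})

test_that("partial-correlation variant rescales the precision matrix", {
  set.seed(14)
  ts <- matrix(rnorm(50 * 4), 50, 4)
  P <- connValues(tikhonovConnectivity(ts, rho = 0.1))
  pc <- connValues(tikhonovConnectivity(ts, rho = 0.1, partialCor = TRUE))
  i <- 1; j <- 3
  expect_equal(pc[i, j], -P[i, j] / sqrt(P[i, i] * P[j, j]))
  expect_equal(diag(pc), rep(1, 4))
})

test_that("proportional threshold retains the floor-count top edges", {
  # counting formula across a range of sizes
  for (n in c(5, 17, 90, 200, 400)) {
    set.seed(n)
    cm <- ConnectivityMatrix(randomSymmetric(n))
    thr <- proportionalThreshold(cm, 0.05)
    kept <- sum(connValues(thr)[upper.tri(connValues(thr))] != 0)
    expect_identical(kept, as.integer(floor(0.05 * n * (n - 1) / 2)))
  }
  # n = 90 gives exactly floor(0.05 * 4005) = 200 edges
  set.seed(1)
  cm90 <- proportionalThreshold(ConnectivityMatrix(randomSymmetric(90)), 0.05)
  expect_identical(sum(connValues(cm90)[upper.tri(connValues(cm90))] != 0),
    200L)
})

test_that("threshold keeps exactly the top-magnitude set, signed", {
  set.seed(15)
  v <- randomSymmetric(12)
  cm <- proportionalThreshold(ConnectivityMatrix(v), 0.3)
  keepRef <- thresholdOracle(v, 0.3)
  ut <- which(upper.tri(v), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), ]
  got <- connValues(cm)[ut]
  expect_equal(got != 0, keepRef)
  expect_equal(got[keepRef], v[ut][keepRef]) # signed weights survive
  expect_true(all(diag(connValues(cm)) == 0))
})

test_that("threshold is idempotent and zeroes an all-zero matrix", {
  set.seed(16)
  cm <- proportionalThreshold(ConnectivityMatrix(randomSymmetric(20)), 0.1)
  again <- proportionalThreshold(cm, 0.1)
  expect_equal(connValues(again), connValues(cm))
  z <- proportionalThreshold(ConnectivityMatrix(matrix(0, 6, 6)), 0.5)
  expect_true(all(connValues(z) == 0))
  expect_error(proportionalThreshold(cm, 1.5), "sparsity")
})

test_that("standardization z-scores retained edges only (population sd)", {
  v <- matrix(0, 4, 4)
  v[1, 2] <- v[2, 1] <- 1
  v[3, 4] <- v[4, 3] <- 3
  cm <- ConnectivityMatrix(v, isThresholded = TRUE)
  s <- connValues(standardizeMatrix(cm))
  expect_equal(s[1, 2], -1) # {1,3} -> +-1 under population sd
  expect_equal(s[3, 4], 1)
  expect_equal(sum(s == 0), 12) # zeros stay zeros
})

test_that("standardized retained edges have mean 0, sd 1, zeros preserved", {
  set.seed(17)
  cm <- proportionalThreshold(ConnectivityMatrix(randomSymmetric(15)), 0.2)
  s <- standardizeMatrix(cm)
  up <- connValues(s)[upper.tri(connValues(s))]
  kept <- up[up != 0]
  expect_lt(abs(mean(kept)), 1e-12)
  expect_lt(abs(sqrt(mean((kept - mean(kept))^2)) - 1), 1e-12)
  expect_identical(sum(up == 0), sum(connValues(cm)[upper.tri(connValues(cm))] == 0))
  expect_lt(max(abs(connValues(s) - t(connValues(s)))), 1e-12)
})

test_that("standardization rejects degenerate inputs", {
  v <- matrix(0, 3, 3)
  v[1, 2] <- v[2, 1] <- 2
  v[1, 3] <- v[3, 1] <- 2
  cm <- ConnectivityMatrix(v, isThresholded = TRUE)
  expect_error(standardizeMatrix(cm), "zero variance")
  expect_error(standardizeMatrix(ConnectivityMatrix(randomSymmetric(5))),
    "thresholded")
})

test_that("residualization removes a planted age effect", {
  set.seed(18)
  N <- 500; n <- 8
  age <- runif(N, 7, 30)
  mats <- lapply(seq_len(N), function(k) {
    m <- randomSymmetric(n)
    m[1, 2] <- m[2, 1] <- 2 * age[k] + rnorm(1)
    m
  })
  ph <- data.frame(
    subject_id = sprintf("s%03d", 1:N), site = "A", age = age,
    sex = rbinom(N, 1, 0.5), score = rnorm(N)
  )
  coh <- ConnectivityCohort(mats, ph, targetName = "score")
  md <- S4Vectors::metadata(coh)
  md$isThresholded <- TRUE # treat all edges as retained
  S4Vectors::metadata(coh) <- md
  res <- residualizeCovariates(coh, c("age", "sex"))
  edge <- vapply(seq_len(N), function(k) connMatrix(res, k)[1, 2], numeric(1))
  expect_lt(abs(cor(edge, age)), 0.05)
})

test_that("residuals are orthogonal to the design on fit rows", {
  set.seed(19)
  coh <- tinyCohort(N = 40, n = 6)
  res <- residualizeCovariates(coh, c("site", "age", "sex"))
  ph <- as.data.frame(SummarizedExperiment::colData(res))
  X <- severityNet:::covariateDesign(ph, c("site", "age", "sex"))
  E <- vapply(seq_len(40), function(k) connMatrix(res, k)[1, 2], numeric(1))
  expect_lt(max(abs(crossprod(X, E))), 1e-8)
})

test_that("single-site no-covariate residualization mean-centers edges", {
  set.seed(20)
  N <- 10; n <- 5
  mats <- lapply(seq_len(N), function(k) randomSymmetric(n))
  ph <- data.frame(
    subject_id = sprintf("s%02d", 1:N), site = "only",
    age = runif(N, 8, 20), sex = 0, score = rnorm(N)
  )
  coh <- ConnectivityCohort(mats, ph, targetName = "score")
  res <- residualizeCovariates(coh, "site") # single site: intercept only
  e12 <- vapply(seq_len(N), function(k) connMatrix(coh, k)[1, 2], numeric(1))
  r12 <- vapply(seq_len(N), function(k) connMatrix(res, k)[1, 2], numeric(1))
  expect_equal(r12, e12 - mean(e12), tolerance = 1e-12)
})

test_that("residualization rejects rank-deficient designs", {
  set.seed(21)
  N <- 8
  mats <- lapply(seq_len(N), function(k) randomSymmetric(5))
  ph <- data.frame(
    subject_id = sprintf("s%02d", 1:N), site = sprintf("s%02d", 1:N),
    age = runif(N), sex = rbinom(N, 1, 0.5), score = rnorm(N)
  ) # one subject per site: site dummies collinear with everything
  coh <- ConnectivityCohort(mats, ph, targetName = "score")
  expect_error(residualizeCovariates(coh, c("site", "age", "sex")),
    "collinear|fit rows")
})

test_that("full build pipeline is deterministic", {
  coh <- tinyCohort(N = 8, n = 12)
  b1 <- buildCohort(coh, sparsity = 0.2)
  b2 <- buildCohort(coh, sparsity = 0.2)
  expect_identical(
    SummarizedExperiment::assay(b1, "connectivity"),
    SummarizedExperiment::assay(b2, "connectivity")
  )
  expect_true(isThresholded(b1) && isStandardized(b1))
})
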