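#' Leaky rectified linear unit
#'
#' Identity for nonnegative inputs, `slope * x` otherwise. The default slope
#' of 1/3 is the activation used throughout the network.
#'
#' @param x Numeric vector, matrix or array.
#' @param slope Negative-side slope (default 1/3).
#' @return Object of the same shape as `x`.
#' @export
#' @examples
#' leakyRelu(c(-3, 0, 2))
leakyRelu <- function(x, slope = 1 / 3) {
  (x >= 0) * x + slope * ((x < 0) * x)
}

## derivative of leakyRelu w.r.t. its pre-activation; subgradient 1 at 0
lreluGrad <- function(x, slope = 1 / 3) {
  (x >= 0) + slope * (x < 0)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' @keywords internal
## run expr under a temporary RNG state; the caller's stream is untouched
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## upper-triangle index pairs (i < j) in lexicographic (i, j) order
upperTriPairs <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

## fill a symmetric matrix from upper-triangle values in lexicographic order
symFromUpper <- function(vals, n, diag = 0) {
  m <- matrix(0, n, n)
  p <- upperTriPairs(n)
  m[p] <- vals
  m[p[, c(2L, 1L)]] <- vals
  diag(m) <- diag
  m
}

upperValues <- function(m) {
  m[upperTriPairs(nrow(m))]
}

checkSymmetric <- function(m, tol = 1e-9, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix", call. = FALSE)
  if (max(abs(m - t(m))) > tol)
    stop(what, " is not symmetric within ", tol, call. = FALSE)
  invisible(TRUE)
}
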