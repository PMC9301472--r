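#' Initialize model parameters
#'
#' Draws every weight from a zero-mean Gaussian with variance `2 / fan_in`
#' (He initialization) and sets all biases to zero. The fan-in of an
#' edge-to-edge filter is `2 n d_in` (row plus column kernel over all input
#' maps), of an edge-to-node filter `n d_in`, of a GCN weight its input
#' width, and of a dense layer its input size. Deterministic given `seed`;
#' the caller's RNG stream is untouched.
#'
#' @param config A [ModelConfig-class].
#' @param seed Integer seed.
#' @return Named list of parameter arrays: `e2e` (per layer, row kernels `r`
#'   and column kernels `c`, each `n x d_in x d_out`), `e2n` (`n x d x d`),
#'   `embedR`/`embedC` (`n x d`, e2e adjacency mode only), `att` (per layer
#'   `W0` (`m x p`) and `W1` (`p x 1`)), and `mlp` (`W`, `b` lists).
#' @export
initParams <- function(config, seed = 1L) {
  n <- config@nROIs
  d <- config@nMaps
  withSeed(seed, {
    he <- function(dims, fanIn) array(rnorm(prod(dims), sd = sqrt(2 / fanIn)),
      dim = dims)
    dIn <- c(1L, rep(d, config@nE2ELayers - 1L))
    e2e <- lapply(seq_len(config@nE2ELayers), function(l) {
      list(
        r = he(c(n, dIn[l], d), 2 * n * dIn[l]),
        c = he(c(n, dIn[l], d), 2 * n * dIn[l])
      )
    })
    e2n <- he(c(n, d, d), n * d)
    params <- list(e2e = e2e, e2n = e2n)
    if (config@adjacencyMode == "e2e") {
      params$embedR <- he(c(n, d), 2 * n * d)
      params$embedC <- he(c(n, d), 2 * n * d)
    }
    params$att <- lapply(seq_len(config@nAttLayers), function(l) {
      list(W0 = he(c(d, config@pAtt), d), W1 = he(c(config@pAtt, 1L), config@pAtt))
    })
    sizes <- c(2L * d, config@mlpSizes, 1L)
    params$mlp <- list(
      W = lapply(seq_len(length(sizes) - 1L), function(i) {
        he(c(sizes[i], sizes[i + 1]), sizes[i])
      }),
      b = lapply(seq_len(length(sizes) - 1L), function(i) numeric(sizes[i + 1]))
    )
    params
  })
}

## recursively apply f over numeric leaves of two parallel parameter lists
mapParams <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- mapParams(a[[nm]], b[[nm]], f)
    return(out)
  }
  f(a, b)
}

## recursively apply f over numeric leaves of one parameter list
mapParams1 <- function(a, f) {
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- mapParams1(a[[nm]], f)
    return(a)
  }
  f(a)
}

## flatten parameters to one numeric vector (finite-difference tests)
paramsToVector <- function(p) {
  unlist(p, use.names = FALSE)
}

## inverse of paramsToVector
vectorToParams <- function(v, template) {
  pos <- 0L
  fill <- function(x) {
    if (is.list(x)) {
      for (i in seq_along(x)) x[[i]] <- fill(x[[i]])
      return(x)
    }
    len <- length(x)
    out <- v[(pos + 1L):(pos + len)]
    pos <<- pos + len
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  fill(template)
}

zeroLike <- function(p) mapParams1(p, function(x) x * 0)
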