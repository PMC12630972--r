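#' Order-statistics layer
#'
#' Per-pixel channel-wise extreme-value pooling: for every spatial
#' location the layer computes the mean of the `k` smallest and the `k`
#' largest values across channels, normalizes both by the large-order
#' statistic, and concatenates the two resulting maps to the input as
#' additional channels. With `k = 1` the appended channels are the plain
#' per-pixel channel minimum and maximum (normalized). The layer has no
#' learnable parameters and is placed after the bottleneck's first
#' ReLU-activated convolution, so its input is nonnegative by
#' construction.
#'
#' @param x feature tensor, an `H x W x C` or `H x W x C x N` numeric
#'   array with nonnegative, finite values.
#' @param k integer, number of extreme channels averaged (1 <= k <= C).
#' @param eps small positive constant preventing division by zero.
#' @return For `channelOrderStats`, a list with `small` and `large`
#'   (`H x W x 1 x N` arrays). For `normalizeOrders`, a list with
#'   `smallNorm` and `largeNorm`, both in `[0, 1)`. For `oslForward`,
#'   an `H x W x (C+2) x N` array whose first `C` channels are the input
#'   unchanged, followed by the normalized small- and large-order maps.
#' @examples
#' x <- array(c(1, 2, 3, 4), dim = c(1, 1, 4))
#' channelOrderStats(x, k = 2)          # means 1.5 and 3.5
#' dim(oslForward(array(runif(8 * 8 * 16), c(8, 8, 16))))
#' @export
channelOrderStats <- function(x, k = 1L) {
  x <- as4d(x)
  C <- dim(x)[3]
  k <- as.integer(k)
  if (k < 1L || k > C)
    stop("k must lie in [1, C]; got k = ", k, " with C = ", C)
  if (!all(is.finite(x))) stop("feature tensor must be finite")
  st <- .osl_stats(x, k)
  list(small = st$small, large = st$large)
}

#' @rdname channelOrderStats
#' @param small,large small- and large-order maps as returned by
#'   `channelOrderStats` (pointwise `small <= large`, both nonnegative).
#' @export
normalizeOrders <- function(small, large, eps = 1e-7) {
  if (any(small < 0) || any(large < 0))
    stop("order statistics must be nonnegative (layer expects post-ReLU input)")
  if (any(small > large))
    stop("small-order statistic exceeds large-order statistic")
  den <- large + eps
  list(smallNorm = small / den, largeNorm = large / den)
}

#' @rdname channelOrderStats
#' @export
oslForward <- function(x, k = 1L, eps = 1e-7) {
  x <- as4d(x)
  if (any(x < 0))
    stop("order-statistics layer expects nonnegative (post-ReLU) input")
  st <- channelOrderStats(x, k)
  nrm <- normalizeOrders(st$small, st$large, eps)
  concatC(x, nrm$smallNorm, nrm$largeNorm)
}

# forward with cache for backprop (internal)
oslFw <- function(x, k, eps) {
  st <- .osl_stats(x, k)
  den <- st$large + eps
  sn <- st$small / den
  ln <- st$large / den
  list(y = concatC(x, sn, ln), st = st, den = den, eps = eps, k = k)
}

# backward: dy has C + 2 channels; returns dx with C channels
oslBw <- function(cache, dy) {
  C <- dim(dy)[3] - 2L
  parts <- splitC(dy, c(C, 1L, 1L))
  dsn <- parts[[2]]
  dln <- parts[[3]]
  den <- cache$den
  dsmall <- dsn / den
  dlarge <- -dsn * cache$st$small / den^2 + dln * cache$eps / den^2
  parts[[1]] + .osl_bw(dsmall, dlarge, cache$st$small_idx,
                       cache$st$large_idx, C)
}
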