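# Internal network primitives. Tensors are numeric arrays with dim
# (H, W, C, N). Every layer comes as a fw/bw pair; forward returns what
# the backward pass needs in addition to its output.

as4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected a 2-4 dimensional array")
  x
}

# evaluate expr under a temporary RNG seed, restoring the caller's state
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# broadcast a per-channel vector over an (H, W, C, N) tensor
bcastC <- function(v, d) {
  array(rep(rep(v, each = d[1] * d[2]), times = d[4]), dim = d)
}

# per-channel sum over (H, W, N)
chanSum <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2])            # (H*W) x (C*N)
  s <- colSums(m)
  rowSums(matrix(s, nrow = d[3]))
}

reluFw <- function(x) pmax(x, 0)
reluBw <- function(x, dy) dy * (x > 0)

sigmoidFw <- function(x) 1 / (1 + exp(-x))

concatC <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], integer(1))
  out <- array(0, dim = c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (x in xs) {
    cc <- dim(x)[3]
    out[, , at + seq_len(cc), ] <- x
    at <- at + cc
  }
  out
}

splitC <- function(dy, sizes) {
  at <- 0L
  lapply(sizes, function(cc) {
    sl <- dy[, , at + seq_len(cc), , drop = FALSE]
    at <<- at + cc
    sl
  })
}

upsample2Fw <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

upsample2Bw <- function(dy) {
  d <- dim(dy)
  o <- seq(1L, d[1], by = 2L)
  e <- seq(2L, d[1], by = 2L)
  ow <- seq(1L, d[2], by = 2L)
  ew <- seq(2L, d[2], by = 2L)
  dy[o, ow, , , drop = FALSE] + dy[e, ow, , , drop = FALSE] +
    dy[o, ew, , , drop = FALSE] + dy[e, ew, , , drop = FALSE]
}

# batch normalization over (H, W, N) per channel
bnFw <- function(x, gamma, beta, stats, training, momentum = 0.1,
                 eps = 1e-5) {
  d <- dim(x)
  if (training) {
    m <- d[1] * d[2] * d[4]
    mu <- chanSum(x) / m
    xc <- x - bcastC(mu, d)
    v <- chanSum(xc * xc) / m
    ivar <- 1 / sqrt(v + eps)
    xhat <- xc * bcastC(ivar, d)
    stats$mean <- (1 - momentum) * stats$mean + momentum * mu
    stats$var <- (1 - momentum) * stats$var + momentum * v
  } else {
    ivar <- 1 / sqrt(stats$var + eps)
    xhat <- (x - bcastC(stats$mean, d)) * bcastC(ivar, d)
  }
  y <- xhat * bcastC(gamma, d) + bcastC(beta, d)
  list(y = y, xhat = xhat, ivar = ivar, stats = stats)
}

bnBw <- function(cache, gamma, dy) {
  d <- dim(dy)
  m <- d[1] * d[2] * d[4]
  dgamma <- chanSum(dy * cache$xhat)
  dbeta <- chanSum(dy)
  dxhat <- dy * bcastC(gamma, d)
  dx <- (dxhat * m - bcastC(chanSum(dxhat), d) -
           cache$xhat * bcastC(chanSum(dxhat * cache$xhat), d)) *
    bcastC(cache$ivar, d) / m
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

dropoutFw <- function(x, rate) {
  if (rate <= 0) return(list(y = x, mask = NULL))
  mask <- array((runif(length(x)) >= rate) / (1 - rate), dim = dim(x))
  list(y = x * mask, mask = mask)
}

dropoutBw <- function(mask, dy) if (is.null(mask)) dy else dy * mask

# He-normal initialized convolution kernel (kh, kw, cin, cout)
initConv <- function(kh, kw, cin, cout) {
  sd <- sqrt(2 / (kh * kw * cin))
  array(rnorm(kh * kw * cin * cout, sd = sd), dim = c(kh, kw, cin, cout))
}
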