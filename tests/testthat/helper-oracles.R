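# Independent brute-force oracles and in-memory fixture builders shared
# across the suite. Oracles deliberately use naive per-pixel loops /
# sorts so they stay independent of the implementation they check.

# neighborhood min/max with the window clipped at the image border
bruteMinMax <- function(img, kh, kw, takeMax) {
  storage.mode(img) <- "double"
  H <- nrow(img); W <- ncol(img)
  rh <- (kh - 1) / 2; rw <- (kw - 1) / 2
  out <- img
  for (i in seq_len(H)) {
    ri <- max(1, i - rh):min(H, i + rh)
    for (j in seq_len(W)) {
      rj <- max(1, j - rw):min(W, j + rw)
      out[i, j] <- if (takeMax) max(img[ri, rj]) else min(img[ri, rj])
    }
  }
  out
}

bruteBlackHat <- function(img, kh, kw) {
  storage.mode(img) <- "double"
  bruteMinMax(bruteMinMax(img, kh, kw, TRUE), kh, kw, FALSE) - img
}

# per-pixel sort-and-average order statistics
bruteOrderStats <- function(x, k) {
  d <- dim(x)
  small <- array(0, c(d[1], d[2], 1, d[4]))
  large <- array(0, c(d[1], d[2], 1, d[4]))
  for (n in seq_len(d[4])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    v <- sort(x[i, j, , n])
    small[i, j, 1, n] <- mean(v[seq_len(k)])
    large[i, j, 1, n] <- mean(rev(v)[seq_len(k)])
  }
  list(small = small, large = large)
}

# exhaustive threshold-sweep trapezoid AUC
bruteAuc <- function(prob, truth) {
  p <- as.vector(prob); y <- as.vector(truth)
  ths <- sort(unique(c(-Inf, p, Inf)), decreasing = TRUE)
  tpr <- fpr <- numeric(length(ths))
  npos <- sum(y == 1); nneg <- sum(y == 0)
  for (i in seq_along(ths)) {
    pred <- p >= ths[i]
    tpr[i] <- sum(pred & y == 1) / npos
    fpr[i] <- sum(pred & y == 0) / nneg
  }
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# analytic parameter count for the configured topology
countParamsOracle <- function(cfg) {
  nE <- length(cfg@encoderFilters)
  ef <- cfg@encoderFilters
  fb <- cfg@bottleneckFilters
  n <- 0
  cin <- cfg@inChannels
  for (i in seq_len(nE)) {
    n <- n + 9 * cin * ef[i] + ef[i] + 9 * ef[i] * ef[i] + ef[i]
    cin <- ef[i]
  }
  n <- n + 9 * cin * fb + fb
  botIn <- if (cfg@useOSL) fb + 2 else fb
  n <- n + 9 * botIn * fb + fb
  prevC <- fb
  for (j in seq_len(nE)) {
    dj <- rev(ef)[j]
    skipC <- ef[nE + 1 - j]
    n <- n + 9 * prevC * dj + dj
    if (cfg@useAttention) {
      inter <- max(1, skipC %/% 2)
      n <- n + skipC * inter + inter + prevC * inter + inter + inter + 1
    }
    catC <- dj + skipC
    if (cfg@useFeedback) {
      n <- n + dj * cfg@feedbackChannels + cfg@feedbackChannels
      catC <- catC + cfg@feedbackChannels
    }
    n <- n + 9 * catC * dj + dj + 2 * dj   # c1 + bn1
    n <- n + 9 * dj * dj + dj + 2 * dj     # c2 + bn2
    n <- n + 9 * dj * dj + dj              # cf
    prevC <- dj
  }
  n + prevC + 1                            # 1x1 head
}

# direct simulation of the plateau / early-stop counter rules
oracleSchedule <- function(improves, lr0 = 1e-4, factor = 0.1,
                           lrPatience = 10, stopPatience = 15) {
  lr <- lr0; lrStall <- 0; esStall <- 0
  stopEpoch <- NA_integer_
  lrs <- numeric(length(improves))
  for (e in seq_along(improves)) {
    if (improves[e]) {
      lrStall <- 0; esStall <- 0
    } else {
      lrStall <- lrStall + 1
      esStall <- esStall + 1
      if (lrStall >= lrPatience) { lr <- lr * factor; lrStall <- 0 }
    }
    lrs[e] <- lr
    if (is.na(stopEpoch) && esStall >= stopPatience) stopEpoch <- e
  }
  list(lrs = lrs, stopEpoch = stopEpoch)
}

# turn an improve/stall pattern into a concrete loss sequence: an
# improvement beats the running best by 2x minDelta, a stall repeats it
lossesFromPattern <- function(improves, minDelta = 1e-4) {
  best <- 1
  losses <- numeric(length(improves))
  for (e in seq_along(improves)) {
    losses[e] <- if (improves[e]) best - 2 * minDelta else best
    if (improves[e]) best <- losses[e]
  }
  losses
}

# in-memory synthetic dataset (no disk I/O)
makeSceneData <- function(n, size = 64, seedBase = 10000,
                          hair = hairSpec(), lowContrastFrac = 0.3) {
  imgs <- array(0, c(size, size, 3, n))
  msks <- array(0, c(size, size, 1, n))
  for (i in seq_len(n)) {
    s <- dermseg:::sampleScene(size, size, hair = hair,
                               lowContrastFrac = lowContrastFrac,
                               seed = seedBase + i)
    imgs[, , , i] <- s$image / 255
    msks[, , 1, i] <- s$mask
  }
  list(images = imgs, masks = msks)
}

tinyConfig <- function(...) {
  ModelConfig(encoderFilters = c(2L, 3L), bottleneckFilters = 4L,
              inputSize = 32L, dropoutRate = 0, feedbackChannels = 3L,
              ...)
}
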