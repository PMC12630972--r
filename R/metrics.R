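# Segmentation losses and evaluation metrics. Masks are binary arrays
# ({0,1}, or {0,255} in file form, coerced by asBinary); the lesion is
# the positive class throughout.

asBinary <- function(m) {
  m <- as.array(m)
  u <- unique(as.vector(m))
  if (!all(u %in% c(0, 1))) {
    if (all(u %in% c(0, 255))) m <- m / 255
    else stop("mask values must be {0,1} or {0,255}")
  }
  m
}

#' Pixelwise confusion counts
#'
#' @param pred,truth binary masks of identical shape ({0,1} or {0,255}).
#' @return named numeric vector with `TP`, `FP`, `FN`, `TN`.
#' @export
confusionCounts <- function(pred, truth) {
  pred <- asBinary(pred); truth <- asBinary(truth)
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and truth shapes differ")
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' Dice coefficient and Jaccard index
#'
#' Overlap measures between a predicted and a reference binary mask:
#' Dice = 2|A intersect B| / (|A| + |B|) and IoU = |A intersect B| /
#' |A union B| = Dice / (2 - Dice). When both masks are empty the
#' overlap is perfect by convention and both return 1.
#'
#' @param pred,truth binary masks of identical shape.
#' @return a number in `[0, 1]`.
#' @examples
#' a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
#' diceCoef(a, a)  # 1
#' iouCoef(a, 1 - a)  # 0
#' @export
diceCoef <- function(pred, truth) {
  pred <- asBinary(pred); truth <- asBinary(truth)
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and truth shapes differ")
  i <- sum(pred * truth)
  s <- sum(pred) + sum(truth)
  if (s == 0) 1.0 else 2 * i / s
}

#' @rdname diceCoef
#' @export
iouCoef <- function(pred, truth) {
  pred <- asBinary(pred); truth <- asBinary(truth)
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and truth shapes differ")
  i <- sum(pred * truth)
  u <- sum(pmax(pred, truth))
  if (u == 0) 1.0 else i / u
}

#' Pixel accuracy, precision and recall from confusion counts
#'
#' A zero denominator with a zero error count returns 1 (a degenerate
#' but perfect prediction); a zero denominator with errors returns 0.
#'
#' @param counts named vector as returned by [confusionCounts()].
#' @return named numeric vector `pixel_accuracy`, `precision`, `recall`.
#' @export
basicRates <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  fn <- counts[["FN"]]; tn <- counts[["TN"]]
  total <- tp + fp + fn + tn
  safe <- function(num, den, err) {
    if (den > 0) num / den else if (err == 0) 1.0 else 0.0
  }
  c(pixel_accuracy = if (total > 0) (tp + tn) / total else 1.0,
    precision = safe(tp, tp + fp, fn),
    recall = safe(tp, tp + fn, fp))
}

#' Area under the ROC curve
#'
#' Computed over pooled pixels with the Mann-Whitney rank statistic
#' (midranks for ties), i.e. the probability that a random lesion pixel
#' receives a higher score than a random background pixel.
#'
#' @param probabilities numeric scores in `[0, 1]`.
#' @param truth binary mask of the same length/shape.
#' @return AUC in `[0, 1]`, or `NA` if the truth contains one class only.
#' @export
rocAuc <- function(probabilities, truth) {
  truth <- asBinary(truth)
  p <- as.vector(probabilities)
  y <- as.vector(truth)
  if (length(p) != length(y)) stop("length mismatch")
  npos <- as.numeric(sum(y == 1)); nneg <- as.numeric(sum(y == 0))
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Hybrid Dice + binary cross-entropy loss
#'
#' The training objective: `wDice * (1 - softDice) + wBce * meanBCE`,
#' where the soft Dice uses probabilities directly with additive
#' smoothing 1 in numerator and denominator (computed per image, then
#' averaged), and probabilities are clipped at 1e-7 for the BCE term.
#'
#' @param probabilities `H x W (x 1 x N)` array of probabilities.
#' @param truth binary mask array of matching spatial shape.
#' @param wDice,wBce nonnegative loss weights (defaults 0.5 each).
#' @return a nonnegative scalar.
#' @export
hybridLoss <- function(probabilities, truth, wDice = 0.5, wBce = 0.5) {
  if (wDice < 0 || wBce < 0) stop("loss weights must be nonnegative")
  hybridLossGrad(probabilities, truth, wDice, wBce, grad = FALSE)$loss
}

# loss + gradient wrt probabilities (internal); smoothing s = 1,
# clip delta = 1e-7
hybridLossGrad <- function(p, y, wDice, wBce, grad = TRUE) {
  p <- as4d(p)
  y <- as4d(asBinary(y))
  if (!identical(dim(p), dim(y))) stop("probability/truth shape mismatch")
  d <- dim(p)
  N <- d[4]; npix <- d[1] * d[2] * d[3]
  s <- 1
  delta <- 1e-7
  pc <- pmin(pmax(p, delta), 1 - delta)

  pm <- matrix(p, nrow = npix)
  ym <- matrix(y, nrow = npix)
  num <- 2 * colSums(pm * ym) + s
  den <- colSums(pm) + colSums(ym) + s
  diceSoft <- num / den
  bce <- -mean(ym * log(matrix(pc, nrow = npix)) +
                 (1 - ym) * log(1 - matrix(pc, nrow = npix)))
  loss <- wDice * (1 - mean(diceSoft)) + wBce * bce
  if (!grad) return(list(loss = loss))

  dDice <- matrix(0, npix, N)
  for (n in seq_len(N)) {
    dDice[, n] <- (2 * ym[, n] * den[n] - num[n]) / den[n]^2
  }
  dp <- -wDice * dDice / N +
    wBce * (matrix(pc, nrow = npix) - ym) /
      (matrix(pc, nrow = npix) * (1 - matrix(pc, nrow = npix))) /
      (npix * N)
  dp <- array(dp, dim = d)
  list(loss = loss, dp = dp, pclip = pc)
}

#' Evaluate a model on a labeled image set
#'
#' Binarizes predicted probabilities at `threshold` and aggregates
#' metrics: Dice and Jaccard as per-image means; pixel accuracy,
#' precision, recall and AUC over pooled pixels. Images whose truth is
#' single-class are excluded from the AUC pool only if the whole pool is
#' single-class (AUC is then `NA`).
#'
#' @param model a [SegModel-class].
#' @param images `H x W x C x N` array in `[0, 1]`.
#' @param masks `H x W x 1 x N` (or `H x W x N`) binary array.
#' @param threshold binarization threshold for predicted masks.
#' @param batchSize images per forward pass.
#' @return a [MetricsReport-class].
#' @export
evaluateModel <- function(model, images, masks, threshold = 0.5,
                          batchSize = 8L) {
  images <- as4d(images)
  masks <- as4d(asBinary(masks))
  if (dim(masks)[3] != 1) stop("masks must be single-channel")
  N <- dim(images)[4]
  if (N == 0 || dim(masks)[4] != N) stop("empty dataset or size mismatch")
  probs <- array(0, dim = dim(masks))
  for (at in seq(1L, N, by = batchSize)) {
    idx <- at:min(N, at + batchSize - 1L)
    probs[, , , idx] <- predictProb(model, images[, , , idx, drop = FALSE])
  }
  reportMetrics(probs, masks, threshold)
}

# aggregate metrics from probability maps (internal; also used on
# cached predictions)
reportMetrics <- function(probs, masks, threshold = 0.5) {
  N <- dim(masks)[4]
  pred <- (probs > threshold) * 1
  dice <- numeric(N); iou <- numeric(N)
  for (n in seq_len(N)) {
    dice[n] <- diceCoef(pred[, , , n], masks[, , , n])
    iou[n] <- iouCoef(pred[, , , n], masks[, , , n])
  }
  counts <- confusionCounts(pred, masks)
  rates <- basicRates(counts)
  auc <- rocAuc(probs, masks)
  new("MetricsReport",
      dice = mean(dice), iou = mean(iou),
      pixelAccuracy = rates[["pixel_accuracy"]],
      precision = rates[["precision"]], recall = rates[["recall"]],
      auc = auc, counts = counts,
      aggregation = "per-image-mean (dice, iou) + pooled (pa, precision, recall, auc)",
      perImage = data.frame(image = seq_len(N), dice = dice, iou = iou))
}
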