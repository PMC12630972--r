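# Training protocol: Adam on the hybrid loss with
# reduce-on-plateau learning-rate decay and early stopping, manifest
# splitting, and the five-configuration ablation harness.

#' Split a manifest into train/validation/test sets
#'
#' Seeded shuffle followed by contiguous assignment of the requested
#' counts, guaranteeing disjoint splits. The default counts are the
#' published primary-dataset split (1815 / 259 / 520 out of 2594).
#'
#' @param records data.frame of manifest rows.
#' @param counts integer vector `c(train, validation, test)`.
#' @param seed integer seed.
#' @return `records` with a `split` column, rows in shuffled order
#'   (unassigned rows, if counts undershoot, are dropped).
#' @export
splitManifest <- function(records, counts = c(1815L, 259L, 520L),
                          seed = 1L) {
  counts <- as.integer(counts)
  if (length(counts) != 3L || any(counts < 0))
    stop("counts must be c(train, validation, test), all >= 0")
  if (sum(counts) > nrow(records))
    stop("requested counts (", sum(counts), ") exceed manifest size (",
         nrow(records), ")")
  idx <- withSeed(seed, sample.int(nrow(records)))
  take <- idx[seq_len(sum(counts))]
  out <- records[take, , drop = FALSE]
  out$split <- rep(c("train", "validation", "test"), counts)
  rownames(out) <- NULL
  out
}

#' Reduce-on-plateau learning-rate state
#'
#' After `patience` consecutive epochs in which the validation loss
#' fails to improve the running best by at least `minDelta`, the
#' learning rate is multiplied by `factor` (not below `floor`) and the
#' stall counter resets.
#'
#' @param lr initial learning rate.
#' @param factor multiplicative decay factor (default 0.1).
#' @param patience stall epochs before decay (default 10).
#' @param minDelta minimum absolute improvement (default 1e-4).
#' @param floor learning-rate lower bound.
#' @return a state list; feed it to [plateauStep()].
#' @export
plateauState <- function(lr = 1e-4, factor = 0.1, patience = 10L,
                         minDelta = 1e-4, floor = 1e-7) {
  stopifnot(patience >= 1, factor > 0, factor < 1)
  list(lr = lr, factor = factor, patience = as.integer(patience),
       minDelta = minDelta, floor = floor, best = Inf, stall = 0L)
}

#' @rdname plateauState
#' @param state the current state.
#' @param valLoss this epoch's validation loss.
#' @return the updated state (fields `lr`, `best`, `stall`).
#' @export
plateauStep <- function(state, valLoss) {
  if (valLoss < state$best - state$minDelta) {
    state$best <- valLoss
    state$stall <- 0L
  } else {
    state$stall <- state$stall + 1L
    if (state$stall >= state$patience) {
      state$lr <- max(state$lr * state$factor, state$floor)
      state$stall <- 0L
    }
  }
  state
}

#' Early-stopping state
#'
#' Signals a stop after `patience` consecutive epochs without the
#' validation loss improving the running best by at least `minDelta`.
#'
#' @param patience stall epochs before stopping (default 15).
#' @param minDelta minimum absolute improvement (default 1e-4).
#' @return a state list; feed it to [earlyStopStep()].
#' @export
earlyStopState <- function(patience = 15L, minDelta = 1e-4) {
  stopifnot(patience >= 1)
  list(patience = as.integer(patience), minDelta = minDelta,
       best = Inf, stall = 0L, stop = FALSE)
}

#' @rdname earlyStopState
#' @param state the current state.
#' @param valLoss this epoch's validation loss.
#' @return the updated state; `state$stop` is `TRUE` when training
#'   should halt.
#' @export
earlyStopStep <- function(state, valLoss) {
  if (valLoss < state$best - state$minDelta) {
    state$best <- valLoss
    state$stall <- 0L
  } else {
    state$stall <- state$stall + 1L
  }
  state$stop <- state$stall >= state$patience
  state
}

adamInit <- function(weights) {
  list(m = lapply(weights, function(w) { w[] <- 0; w }),
       v = lapply(weights, function(w) { w[] <- 0; w }),
       t = 0L)
}

adamStep <- function(weights, grads, st, lr, beta1, beta2, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    weights[[nm]] <- weights[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(weights = weights, st = st)
}

# forward + loss + accuracy over a set, in eval mode, batched
validationPass <- function(model, images, masks, wDice, wBce,
                           batchSize = 8L) {
  N <- dim(images)[4]
  loss <- 0; correct <- 0; total <- 0
  dice <- numeric(N)
  for (at in seq(1L, N, by = batchSize)) {
    idx <- at:min(N, at + batchSize - 1L)
    p <- predictProb(model, images[, , , idx, drop = FALSE])
    y <- masks[, , , idx, drop = FALSE]
    loss <- loss + hybridLoss(p, y, wDice, wBce) * length(idx)
    pred <- (p > 0.5) * 1
    correct <- correct + sum(pred == y)
    total <- total + length(y)
    for (k in seq_along(idx))
      dice[idx[k]] <- diceCoef(pred[, , , k], y[, , , k])
  }
  list(loss = loss / N, acc = correct / total, dice = mean(dice))
}

#' Train a segmentation model
#'
#' Mini-batch Adam on the hybrid Dice + BCE loss with per-epoch
#' validation, reduce-on-plateau learning-rate decay and early
#' stopping; the weights achieving the best validation loss are
#' restored at the end. Augmentation, when given, is applied online to
#' the training stream only, with a fresh transform per (epoch,
#' sample); the validation set is never augmented or shuffled.
#'
#' @param model a freshly built or previously trained [SegModel-class].
#' @param trainImages,trainMasks training set, `H x W x C x N` images in
#'   `[0, 1]` and `H x W x 1 x N` binary masks.
#' @param valImages,valMasks validation set in the same layout.
#' @param config a [TrainConfig-class].
#' @param augment optional [augmentationConfig()] for the training
#'   stream.
#' @param verbose print one line per epoch.
#' @return list with `model` (best weights), `history` (one row per
#'   epoch: losses, accuracies, validation Dice, learning rate) and
#'   `bestEpoch`.
#' @export
trainModel <- function(model, trainImages, trainMasks, valImages,
                       valMasks, config = TrainConfig(), augment = NULL,
                       verbose = FALSE) {
  validObject(config)
  trainImages <- as4d(trainImages); trainMasks <- as4d(trainMasks)
  valImages <- as4d(valImages); valMasks <- as4d(valMasks)
  N <- dim(trainImages)[4]
  if (N == 0 || dim(valImages)[4] == 0) stop("empty training or validation set")

  adam <- adamInit(model@weights)
  plateau <- plateauState(lr = config@lr, factor = config@lrFactor,
                          patience = config@lrPatience,
                          minDelta = config@minDelta,
                          floor = config@lrFloor)
  stopper <- earlyStopState(patience = config@earlyStopPatience,
                            minDelta = config@minDelta)
  best <- list(loss = Inf, weights = model@weights, bn = model@bnStats,
               epoch = 0L)
  history <- list()

  for (epoch in seq_len(config@maxEpochs)) {
    ord <- withSeed(config@seed * 1000L + epoch, sample.int(N))
    epochLoss <- 0; correct <- 0; total <- 0
    for (at in seq(1L, N, by = config@batchSize)) {
      idx <- ord[at:min(N, at + config@batchSize - 1L)]
      xb <- trainImages[, , , idx, drop = FALSE]
      yb <- trainMasks[, , , idx, drop = FALSE]
      if (!is.null(augment)) {
        for (k in seq_along(idx)) {
          ag <- augmentPair(xb[, , , k], yb[, , 1, k], augment,
                            seed = config@seed + epoch * 100000L +
                              idx[k])
          xb[, , , k] <- ag$image
          yb[, , 1, k] <- ag$mask
        }
      }
      # dropout stream seeded per (epoch, batch) for reproducibility
      fw <- withSeed(config@seed * 100L + epoch * 7919L + at,
                     netForward(model, xb, training = TRUE))
      model@bnStats <- fw$bnStats
      lg <- hybridLossGrad(fw$p, yb, config@wDice, config@wBce)
      if (!is.finite(lg$loss))
        stop("training diverged: non-finite loss at epoch ", epoch)
      dz <- lg$dp * fw$p * (1 - fw$p)
      grads <- netBackward(model, fw$cache, dz)
      upd <- adamStep(model@weights, grads, adam, plateau$lr,
                      config@beta1, config@beta2)
      model@weights <- upd$weights
      adam <- upd$st
      epochLoss <- epochLoss + lg$loss * length(idx)
      predb <- (fw$p > 0.5) * 1
      correct <- correct + sum(predb == yb)
      total <- total + length(yb)
    }
    val <- validationPass(model, valImages, valMasks,
                          config@wDice, config@wBce)
    if (val$loss < best$loss) {
      best <- list(loss = val$loss, weights = model@weights,
                   bn = model@bnStats, epoch = epoch)
    }
    plateau <- plateauStep(plateau, val$loss)
    stopper <- earlyStopStep(stopper, val$loss)
    history[[epoch]] <- data.frame(
      epoch = epoch, train_loss = epochLoss / N, train_acc = correct / total,
      val_loss = val$loss, val_acc = val$acc, val_dice = val$dice,
      lr = plateau$lr)
    if (verbose)
      message(sprintf(
        "epoch %3d  train loss %.4f acc %.4f | val loss %.4f acc %.4f dice %.4f | lr %g",
        epoch, epochLoss / N, correct / total, val$loss, val$acc,
        val$dice, plateau$lr))
    if (stopper$stop) break
  }
  model@weights <- best$weights
  model@bnStats <- best$bn
  list(model = model, history = do.call(rbind, history),
       bestEpoch = best$epoch)
}

#' Run the five-configuration ablation study
#'
#' Builds, trains and evaluates the five architecture configurations
#' (baseline with every switch off; attention only; order-statistics
#' layer only; feedback only; and the full model) under a shared seed
#' and epoch budget, and reports Dice, Jaccard and pixel accuracy per
#' configuration.
#'
#' @param trainImages,trainMasks,valImages,valMasks data as in
#'   [trainModel()].
#' @param baseConfig a [ModelConfig-class]; its switches are overridden
#'   per row.
#' @param trainConfig a [TrainConfig-class] (its `maxEpochs` is the
#'   per-configuration budget).
#' @param seed shared seed for weight init and training.
#' @return data.frame with one row per configuration: label, Dice, IoU,
#'   pixel accuracy, and parameter count.
#' @export
runAblation <- function(trainImages, trainMasks, valImages, valMasks,
                        baseConfig = ModelConfig(),
                        trainConfig = TrainConfig(), seed = 1L) {
  switches <- list(
    baseline = c(FALSE, FALSE, FALSE),
    "+attention" = c(TRUE, FALSE, FALSE),
    "+OSL" = c(FALSE, TRUE, FALSE),
    "+feedback" = c(FALSE, FALSE, TRUE),
    full = c(TRUE, TRUE, TRUE))
  rows <- vector("list", length(switches))
  for (i in seq_along(switches)) {
    sw <- switches[[i]]
    cfg <- baseConfig
    cfg@useAttention <- sw[1]
    cfg@useOSL <- sw[2]
    cfg@useFeedback <- sw[3]
    model <- buildModel(cfg, seed = seed)
    tc <- trainConfig
    tc@seed <- as.integer(seed)
    fit <- trainModel(model, trainImages, trainMasks, valImages,
                      valMasks, tc)
    rep <- evaluateModel(fit$model, valImages, valMasks)
    rows[[i]] <- data.frame(
      configuration = names(switches)[i],
      dice = rep@dice, iou = rep@iou, accuracy = rep@pixelAccuracy,
      n_params = nParams(fit$model))
  }
  do.call(rbind, rows)
}
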