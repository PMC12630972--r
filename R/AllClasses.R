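#' Model architecture configuration
#'
#' Describes the encoder-decoder topology and the three architectural
#' switches (attention gates, order-statistics layer, decoder feedback).
#' The defaults reproduce the full model: encoder blocks with 32 and 64
#' 3x3 filters, a 128-filter bottleneck carrying the order-statistics
#' layer, decoder blocks with 64 and 32 filters (mirroring the encoder),
#' dropout 0.3 in the decoder, and two feedback passes.
#'
#' @slot encoderFilters integer vector of filters per encoder block
#'   (decoder blocks mirror it in reverse).
#' @slot bottleneckFilters integer, filters in the bottleneck convolutions.
#' @slot inChannels integer, input image channels (3 for RGB).
#' @slot inputSize integer, expected square input extent in pixels.
#' @slot useAttention,useOSL,useFeedback logical architecture switches.
#' @slot feedbackPasses integer, total forward passes T (>= 1).
#' @slot feedbackChannels integer, channel budget of the 1x1 projection
#'   applied to previous-pass decoder features.
#' @slot dropoutRate numeric in \[0, 1), decoder dropout rate.
#' @slot oslK integer, number of extreme channels averaged per pixel.
#' @slot oslEps numeric, small constant of the order-statistic normalization.
#' @exportClass ModelConfig
setClass("ModelConfig", representation(
  encoderFilters = "integer",
  bottleneckFilters = "integer",
  inChannels = "integer",
  inputSize = "integer",
  useAttention = "logical",
  useOSL = "logical",
  useFeedback = "logical",
  feedbackPasses = "integer",
  feedbackChannels = "integer",
  dropoutRate = "numeric",
  oslK = "integer",
  oslEps = "numeric"
))

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (length(object@encoderFilters) < 1 || any(object@encoderFilters < 1))
    msg <- c(msg, "encoderFilters must be positive counts")
  if (object@bottleneckFilters < 1)
    msg <- c(msg, "bottleneckFilters must be positive")
  if (object@feedbackPasses < 1)
    msg <- c(msg, "feedbackPasses must be >= 1")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must lie in [0, 1)")
  if (object@oslK < 1 || object@oslK > object@bottleneckFilters)
    msg <- c(msg, "oslK must lie in [1, bottleneckFilters]")
  if (object@oslEps <= 0) msg <- c(msg, "oslEps must be > 0")
  if (object@inputSize < 32 || object@inputSize %% 2^(length(object@encoderFilters)) != 0)
    msg <- c(msg, "inputSize must be >= 32 and divisible by 2^depth")
  if (length(msg)) msg else TRUE
})

#' @describeIn ModelConfig-class constructor.
#' @param encoderFilters,bottleneckFilters,inChannels,inputSize,useAttention,useOSL,useFeedback,feedbackPasses,feedbackChannels,dropoutRate,oslK,oslEps see slots.
#' @return a validated `ModelConfig`.
#' @export
ModelConfig <- function(encoderFilters = c(32L, 64L),
                        bottleneckFilters = 128L,
                        inChannels = 3L,
                        inputSize = 256L,
                        useAttention = TRUE,
                        useOSL = TRUE,
                        useFeedback = TRUE,
                        feedbackPasses = 2L,
                        feedbackChannels = 8L,
                        dropoutRate = 0.3,
                        oslK = 1L,
                        oslEps = 1e-7) {
  new("ModelConfig",
      encoderFilters = as.integer(encoderFilters),
      bottleneckFilters = as.integer(bottleneckFilters),
      inChannels = as.integer(inChannels),
      inputSize = as.integer(inputSize),
      useAttention = isTRUE(useAttention),
      useOSL = isTRUE(useOSL),
      useFeedback = isTRUE(useFeedback),
      feedbackPasses = as.integer(feedbackPasses),
      feedbackChannels = as.integer(feedbackChannels),
      dropoutRate = as.numeric(dropoutRate),
      oslK = as.integer(oslK),
      oslEps = as.numeric(oslEps))
}

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig\n")
  cat("  encoder filters:   ", paste(object@encoderFilters, collapse = ", "), "\n")
  cat("  bottleneck filters:", object@bottleneckFilters, "\n")
  cat("  input:             ", object@inputSize, "x", object@inputSize,
      "x", object@inChannels, "\n")
  cat("  attention gates:   ", object@useAttention, "\n")
  cat("  order-stats layer: ", object@useOSL,
      sprintf(" (k = %d, eps = %g)", object@oslK, object@oslEps), "\n")
  cat("  decoder feedback:  ", object@useFeedback,
      sprintf(" (passes = %d, channels = %d)",
              object@feedbackPasses, object@feedbackChannels), "\n")
  cat("  dropout:           ", object@dropoutRate, "\n")
})

#' Segmentation model
#'
#' Container for the network weights, the batch-normalization running
#' statistics, and the architecture configuration that produced them.
#'
#' @slot config the [ModelConfig-class] the weights were built for.
#' @slot weights named list of numeric arrays (kernels, biases, batch
#'   norm scale/shift).
#' @slot bnStats named list of batch-normalization running means and
#'   variances (not trainable parameters).
#' @exportClass SegModel
setClass("SegModel", representation(
  config = "ModelConfig",
  weights = "list",
  bnStats = "list"
))

setMethod("show", "SegModel", function(object) {
  cat("SegModel:", length(object@weights), "weight tensors,",
      format(nParams(object), big.mark = ","), "parameters\n")
  show(object@config)
})

#' @rdname SegModel-class
#' @param object,x a `SegModel`.
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @rdname SegModel-class
#' @export
setMethod("modelConfig", "SegModel", function(x) x@config)

#' @rdname SegModel-class
#' @export
setGeneric("nParams", function(x) standardGeneric("nParams"))

#' @rdname SegModel-class
#' @export
setMethod("nParams", "SegModel", function(x)
  sum(vapply(x@weights, length, integer(1))))

#' Segmentation evaluation report
#'
#' Aggregated metrics over an evaluation set. Dice and Jaccard are
#' per-image means; pixel accuracy, precision, recall and AUC are
#' computed over pooled pixels, following the report's `aggregation`
#' field.
#'
#' @slot dice,iou,pixelAccuracy,precision,recall,auc numeric in \[0, 1\].
#' @slot counts named numeric with pooled TP, FP, FN, TN pixel counts.
#' @slot aggregation character, "per-image-mean+pooled" by default.
#' @slot perImage data.frame of per-image dice and iou.
#' @exportClass MetricsReport
setClass("MetricsReport", representation(
  dice = "numeric", iou = "numeric", pixelAccuracy = "numeric",
  precision = "numeric", recall = "numeric", auc = "numeric",
  counts = "numeric", aggregation = "character", perImage = "data.frame"
))

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport (", object@aggregation, ", ",
      nrow(object@perImage), " images)\n", sep = "")
  v <- c(dice = object@dice, iou = object@iou,
         pixel_accuracy = object@pixelAccuracy,
         precision = object@precision, recall = object@recall,
         auc = object@auc)
  for (nm in names(v)) cat(sprintf("  %-15s %.4f\n", nm, v[[nm]]))
  cat("  counts: TP", object@counts[["TP"]], "FP", object@counts[["FP"]],
      "FN", object@counts[["FN"]], "TN", object@counts[["TN"]], "\n")
})

#' @rdname MetricsReport-class
#' @param x a `MetricsReport`.
#' @param row.names,optional,... passed through (unused).
#' @export
setMethod("as.data.frame", "MetricsReport",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(dice = x@dice, iou = x@iou, pixel_accuracy = x@pixelAccuracy,
               precision = x@precision, recall = x@recall, auc = x@auc,
               TP = x@counts[["TP"]], FP = x@counts[["FP"]],
               FN = x@counts[["FN"]], TN = x@counts[["TN"]])
  })

#' Training protocol configuration
#'
#' Defaults follow the published protocol: Adam (lr 1e-4, beta1 0.9,
#' beta2 0.999), batch size 16, at most 150 epochs, learning rate decay
#' by factor 0.1 after 10 epochs without validation-loss improvement,
#' and early stopping after 15 such epochs.
#'
#' @slot lr,beta1,beta2 Adam hyperparameters.
#' @slot batchSize,maxEpochs integers.
#' @slot lrFactor,lrPatience plateau decay factor and patience (epochs).
#' @slot earlyStopPatience epochs without improvement before stopping.
#' @slot minDelta minimum absolute validation-loss improvement to count.
#' @slot lrFloor lower bound on the learning rate.
#' @slot wDice,wBce hybrid loss weights.
#' @slot seed integer seed controlling shuffling, dropout and augmentation.
#' @exportClass TrainConfig
setClass("TrainConfig", representation(
  lr = "numeric", beta1 = "numeric", beta2 = "numeric",
  batchSize = "integer", maxEpochs = "integer",
  lrFactor = "numeric", lrPatience = "integer",
  earlyStopPatience = "integer", minDelta = "numeric", lrFloor = "numeric",
  wDice = "numeric", wBce = "numeric", seed = "integer"
))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@lrPatience < 1 || object@earlyStopPatience < 1)
    msg <- c(msg, "patiences must be >= 1")
  if (object@lrFactor <= 0 || object@lrFactor >= 1)
    msg <- c(msg, "lrFactor must lie in (0, 1)")
  if (object@batchSize < 1) msg <- c(msg, "batchSize must be >= 1")
  if (object@wDice < 0 || object@wBce < 0)
    msg <- c(msg, "loss weights must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' @describeIn TrainConfig-class constructor.
#' @param lr,beta1,beta2,batchSize,maxEpochs,lrFactor,lrPatience,earlyStopPatience,minDelta,lrFloor,wDice,wBce,seed see slots.
#' @export
TrainConfig <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                        batchSize = 16L, maxEpochs = 150L,
                        lrFactor = 0.1, lrPatience = 10L,
                        earlyStopPatience = 15L, minDelta = 1e-4,
                        lrFloor = 1e-7, wDice = 0.5, wBce = 0.5,
                        seed = 1L) {
  new("TrainConfig", lr = lr, beta1 = beta1, beta2 = beta2,
      batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
      lrFactor = lrFactor, lrPatience = as.integer(lrPatience),
      earlyStopPatience = as.integer(earlyStopPatience),
      minDelta = minDelta, lrFloor = lrFloor,
      wDice = wDice, wBce = wBce, seed = as.integer(seed))
}

setMethod("show", "TrainConfig", function(object) {
  cat("TrainConfig: Adam lr", object@lr,
      sprintf("(beta1 %.3f, beta2 %.3f)", object@beta1, object@beta2),
      "| batch", object@batchSize, "| max epochs", object@maxEpochs, "\n")
  cat("  plateau: factor", object@lrFactor, "patience", object@lrPatience,
      "| early stop patience", object@earlyStopPatience,
      "| min delta", object@minDelta, "\n")
  cat("  loss: ", object@wDice, "* dice +", object@wBce, "* bce | seed",
      object@seed, "\n")
})
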