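# Encoder-decoder assembly. The topology is a two-level (configurable)
# U-Net: encoder blocks of two 3x3 ReLU convolutions followed by 2x2
# max pooling; a bottleneck of two 3x3 ReLU convolutions with the
# order-statistics layer between them; decoder blocks that upsample
# (nearest neighbor + 3x3 convolution), concatenate the (optionally
# attention-gated) encoder skip and the projected previous-pass
# feedback features, and apply two conv+batchnorm+ReLU stages plus a
# final convolution with ReLU and dropout; and a 1x1 sigmoid head.
# With feedback enabled, the decoder runs `feedbackPasses` times; the
# previous pass's decoder outputs are treated as fixed context
# (gradients are not propagated across passes).

decoderChannels <- function(config) {
  rev(config@encoderFilters)
}

#' Build a segmentation model
#'
#' Instantiates seeded He-normal weights for the configured topology.
#' Disabled switches contribute no parameters, so an all-off
#' configuration is a plain U-Net baseline.
#'
#' @param config a [ModelConfig-class].
#' @param seed integer seed for reproducible initialization.
#' @return a [SegModel-class].
#' @examples
#' m <- buildModel(ModelConfig(encoderFilters = c(4L, 8L),
#'                             bottleneckFilters = 16L, inputSize = 64L),
#'                 seed = 1)
#' nParams(m)
#' @export
buildModel <- function(config, seed = 1L) {
  stopifnot(is(config, "ModelConfig"))
  validObject(config)
  nE <- length(config@encoderFilters)
  ef <- config@encoderFilters
  df <- decoderChannels(config)
  fb <- config@bottleneckFilters

  withSeed(seed, {
    w <- list()
    bn <- list()
    cin <- config@inChannels
    for (i in seq_len(nE)) {
      w[[sprintf("enc%d_c1_W", i)]] <- initConv(3, 3, cin, ef[i])
      w[[sprintf("enc%d_c1_b", i)]] <- numeric(ef[i])
      w[[sprintf("enc%d_c2_W", i)]] <- initConv(3, 3, ef[i], ef[i])
      w[[sprintf("enc%d_c2_b", i)]] <- numeric(ef[i])
      cin <- ef[i]
    }
    w$bot_c1_W <- initConv(3, 3, cin, fb)
    w$bot_c1_b <- numeric(fb)
    botIn <- if (config@useOSL) fb + 2L else fb
    w$bot_c2_W <- initConv(3, 3, botIn, fb)
    w$bot_c2_b <- numeric(fb)

    prevC <- fb
    for (j in seq_len(nE)) {
      dj <- df[j]
      skipC <- ef[nE + 1L - j]
      w[[sprintf("dec%d_up_W", j)]] <- initConv(3, 3, prevC, dj)
      w[[sprintf("dec%d_up_b", j)]] <- numeric(dj)
      if (config@useAttention) {
        inter <- max(1L, skipC %/% 2L)
        w[[sprintf("dec%d_att_th_W", j)]] <- initConv(1, 1, skipC, inter)
        w[[sprintf("dec%d_att_th_b", j)]] <- numeric(inter)
        w[[sprintf("dec%d_att_ph_W", j)]] <- initConv(1, 1, prevC, inter)
        w[[sprintf("dec%d_att_ph_b", j)]] <- numeric(inter)
        w[[sprintf("dec%d_att_ps_W", j)]] <- initConv(1, 1, inter, 1L)
        w[[sprintf("dec%d_att_ps_b", j)]] <- numeric(1L)
      }
      catC <- dj + skipC
      if (config@useFeedback) {
        w[[sprintf("dec%d_fb_W", j)]] <- initConv(1, 1, dj, config@feedbackChannels)
        w[[sprintf("dec%d_fb_b", j)]] <- numeric(config@feedbackChannels)
        catC <- catC + config@feedbackChannels
      }
      w[[sprintf("dec%d_c1_W", j)]] <- initConv(3, 3, catC, dj)
      w[[sprintf("dec%d_c1_b", j)]] <- numeric(dj)
      w[[sprintf("dec%d_bn1_g", j)]] <- rep(1, dj)
      w[[sprintf("dec%d_bn1_b", j)]] <- numeric(dj)
      w[[sprintf("dec%d_c2_W", j)]] <- initConv(3, 3, dj, dj)
      w[[sprintf("dec%d_c2_b", j)]] <- numeric(dj)
      w[[sprintf("dec%d_bn2_g", j)]] <- rep(1, dj)
      w[[sprintf("dec%d_bn2_b", j)]] <- numeric(dj)
      w[[sprintf("dec%d_cf_W", j)]] <- initConv(3, 3, dj, dj)
      w[[sprintf("dec%d_cf_b", j)]] <- numeric(dj)
      bn[[sprintf("dec%d_bn1", j)]] <- list(mean = numeric(dj), var = rep(1, dj))
      bn[[sprintf("dec%d_bn2", j)]] <- list(mean = numeric(dj), var = rep(1, dj))
      prevC <- dj
    }
    w$head_W <- initConv(1, 1, prevC, 1L)
    w$head_b <- numeric(1L)
    new("SegModel", config = config, weights = w, bnStats = bn)
  })
}

# multiply an (H, W, C, N) tensor by an (H, W, 1, N) map, broadcasting
# over channels
mulAlpha <- function(x, alpha) {
  C <- dim(x)[3]
  x * alpha[, , rep(1L, C), , drop = FALSE]
}

# Forward pass. Returns the probability map, the cache needed by
# netBackward (final feedback pass only; earlier passes are detached),
# and the (possibly updated) batch-norm running stats.
netForward <- function(model, x, training = FALSE, passes = NULL) {
  cfg <- model@config
  w <- model@weights
  bnStats <- model@bnStats
  x <- as4d(x)
  d <- dim(x)
  if (d[1] != d[2] || d[1] %% 2^length(cfg@encoderFilters) != 0)
    stop("input must be square with dims divisible by 2^depth; got ",
         d[1], "x", d[2])
  if (d[3] != cfg@inChannels)
    stop("input has ", d[3], " channels; model expects ", cfg@inChannels)
  nE <- length(cfg@encoderFilters)
  Tt <- if (!is.null(passes)) as.integer(passes)
        else if (cfg@useFeedback) cfg@feedbackPasses else 1L
  # structure follows the weights: a feedback-built model keeps its
  # (zero-filled on pass 1) feedback channels even when the switch or a
  # passes=1 override reduces it to a single pass
  hasFb <- !is.null(w[["dec1_fb_W"]])

  enc <- vector("list", nE)
  skips <- vector("list", nE)
  cur <- x
  for (i in seq_len(nE)) {
    a1p <- .conv2d_fw(cur, w[[sprintf("enc%d_c1_W", i)]], w[[sprintf("enc%d_c1_b", i)]])
    a1 <- reluFw(a1p)
    a2p <- .conv2d_fw(a1, w[[sprintf("enc%d_c2_W", i)]], w[[sprintf("enc%d_c2_b", i)]])
    a2 <- reluFw(a2p)
    pl <- .maxpool2_fw(a2)
    enc[[i]] <- list(xin = cur, a1p = a1p, a1 = a1, a2p = a2p, a2 = a2,
                     poolIdx = pl$idx)
    skips[[i]] <- a2
    cur <- pl$y
  }

  b1p <- .conv2d_fw(cur, w$bot_c1_W, w$bot_c1_b)
  b1 <- reluFw(b1p)
  if (cfg@useOSL) {
    osl <- oslFw(b1, cfg@oslK, cfg@oslEps)
    be <- osl$y
  } else {
    osl <- NULL
    be <- b1
  }
  b2p <- .conv2d_fw(be, w$bot_c2_W, w$bot_c2_b)
  b2 <- reluFw(b2p)
  bot <- list(xin = cur, b1p = b1p, b1 = b1, osl = osl, be = be, b2p = b2p)

  prevOut <- NULL
  dec <- NULL
  for (t in seq_len(Tt)) {
    last <- t == Tt
    dec <- vector("list", nE)
    cur <- b2
    for (j in seq_len(nE)) {
      g <- cur
      up <- upsample2Fw(cur)
      upp <- .conv2d_fw(up, w[[sprintf("dec%d_up_W", j)]], w[[sprintf("dec%d_up_b", j)]])
      u <- reluFw(upp)
      s <- skips[[nE + 1L - j]]
      att <- NULL
      if (cfg@useAttention) {
        gU <- upsample2Fw(g)
        qp <- .conv2d_fw(s, w[[sprintf("dec%d_att_th_W", j)]], w[[sprintf("dec%d_att_th_b", j)]])
        kp <- .conv2d_fw(gU, w[[sprintf("dec%d_att_ph_W", j)]], w[[sprintf("dec%d_att_ph_b", j)]])
        ap <- qp + kp
        a <- reluFw(ap)
        psip <- .conv2d_fw(a, w[[sprintf("dec%d_att_ps_W", j)]], w[[sprintf("dec%d_att_ps_b", j)]])
        alpha <- sigmoidFw(psip)
        sg <- mulAlpha(s, alpha)
        att <- list(gU = gU, ap = ap, a = a, alpha = alpha)
      } else {
        sg <- s
      }
      fbc <- NULL
      if (hasFb) {
        if (is.null(prevOut)) {
          dd <- dim(u)
          Fv <- array(0, dim = c(dd[1], dd[2], cfg@feedbackChannels, dd[4]))
          fbc <- list(fin = NULL, fp = NULL, Fv = Fv)
        } else {
          fin <- prevOut[[j]]
          fp <- .conv2d_fw(fin, w[[sprintf("dec%d_fb_W", j)]], w[[sprintf("dec%d_fb_b", j)]])
          Fv <- reluFw(fp)
          fbc <- list(fin = fin, fp = fp, Fv = Fv)
        }
        Y <- concatC(u, sg, fbc$Fv)
      } else {
        Y <- concatC(u, sg)
      }
      y1p <- .conv2d_fw(Y, w[[sprintf("dec%d_c1_W", j)]], w[[sprintf("dec%d_c1_b", j)]])
      bn1 <- bnFw(y1p, w[[sprintf("dec%d_bn1_g", j)]], w[[sprintf("dec%d_bn1_b", j)]],
                  bnStats[[sprintf("dec%d_bn1", j)]], training)
      bnStats[[sprintf("dec%d_bn1", j)]] <- bn1$stats
      y1 <- reluFw(bn1$y)
      y2p <- .conv2d_fw(y1, w[[sprintf("dec%d_c2_W", j)]], w[[sprintf("dec%d_c2_b", j)]])
      bn2 <- bnFw(y2p, w[[sprintf("dec%d_bn2_g", j)]], w[[sprintf("dec%d_bn2_b", j)]],
                  bnStats[[sprintf("dec%d_bn2", j)]], training)
      bnStats[[sprintf("dec%d_bn2", j)]] <- bn2$stats
      y2 <- reluFw(bn2$y)
      cfp <- .conv2d_fw(y2, w[[sprintf("dec%d_cf_W", j)]], w[[sprintf("dec%d_cf_b", j)]])
      cf <- reluFw(cfp)
      dop <- dropoutFw(cf, if (training) cfg@dropoutRate else 0)
      out <- dop$y
      if (last) {
        dec[[j]] <- list(xin = g, up = up, upp = upp, u = u, s = s,
                         att = att, fbc = fbc, Y = Y,
                         y1p = y1p, bn1 = bn1, y1 = y1,
                         y2p = y2p, bn2 = bn2, y2 = y2,
                         cfp = cfp, dropMask = dop$mask, out = out)
      } else {
        dec[[j]] <- list(out = out)
      }
      cur <- out
    }
    prevOut <- lapply(dec, `[[`, "out")
  }

  zp <- .conv2d_fw(cur, w$head_W, w$head_b)
  p <- sigmoidFw(zp)
  list(p = p,
       cache = list(x = x, enc = enc, bot = bot, dec = dec, top = cur,
                    Tt = Tt),
       bnStats = bnStats)
}

# Backward pass for the final feedback pass. `dz` is the gradient of
# the loss with respect to the pre-sigmoid head activations.
netBackward <- function(model, cache, dz) {
  cfg <- model@config
  w <- model@weights
  nE <- length(cfg@encoderFilters)
  g <- lapply(w, function(z) { z[] <- 0; z })

  bw <- .conv2d_bw(cache$top, w$head_W, dz)
  g$head_W <- bw$dw; g$head_b <- bw$db
  dX <- bw$dx

  dskips <- vector("list", nE)
  for (j in rev(seq_len(nE))) {
    dc <- cache$dec[[j]]
    dcf <- dropoutBw(dc$dropMask, dX)
    dcfp <- reluBw(dc$cfp, dcf)
    bw <- .conv2d_bw(dc$y2, w[[sprintf("dec%d_cf_W", j)]], dcfp)
    g[[sprintf("dec%d_cf_W", j)]] <- bw$dw
    g[[sprintf("dec%d_cf_b", j)]] <- bw$db
    dy2 <- reluBw(dc$bn2$y, bw$dx)
    bnb <- bnBw(dc$bn2, w[[sprintf("dec%d_bn2_g", j)]], dy2)
    g[[sprintf("dec%d_bn2_g", j)]] <- bnb$dgamma
    g[[sprintf("dec%d_bn2_b", j)]] <- bnb$dbeta
    bw <- .conv2d_bw(dc$y1, w[[sprintf("dec%d_c2_W", j)]], bnb$dx)
    g[[sprintf("dec%d_c2_W", j)]] <- bw$dw
    g[[sprintf("dec%d_c2_b", j)]] <- bw$db
    dy1 <- reluBw(dc$bn1$y, bw$dx)
    bnb <- bnBw(dc$bn1, w[[sprintf("dec%d_bn1_g", j)]], dy1)
    g[[sprintf("dec%d_bn1_g", j)]] <- bnb$dgamma
    g[[sprintf("dec%d_bn1_b", j)]] <- bnb$dbeta
    bw <- .conv2d_bw(dc$Y, w[[sprintf("dec%d_c1_W", j)]], bnb$dx)
    g[[sprintf("dec%d_c1_W", j)]] <- bw$dw
    g[[sprintf("dec%d_c1_b", j)]] <- bw$db
    dY <- bw$dx

    cu <- dim(dc$u)[3]
    cs <- dim(dc$s)[3]
    if (!is.null(w[[sprintf("dec%d_fb_W", j)]])) {
      parts <- splitC(dY, c(cu, cs, cfg@feedbackChannels))
      dF <- parts[[3]]
      if (!is.null(dc$fbc$fin)) {
        dfp <- reluBw(dc$fbc$fp, dF)
        bw <- .conv2d_bw(dc$fbc$fin, w[[sprintf("dec%d_fb_W", j)]], dfp)
        g[[sprintf("dec%d_fb_W", j)]] <- bw$dw
        g[[sprintf("dec%d_fb_b", j)]] <- bw$db
        # dx to the previous pass is dropped: feedback is detached
      }
    } else {
      parts <- splitC(dY, c(cu, cs))
    }
    du <- parts[[1]]
    dsg <- parts[[2]]

    dgAtt <- NULL
    if (cfg@useAttention) {
      at <- dc$att
      ds <- mulAlpha(dsg, at$alpha)
      dalphaFull <- dsg * dc$s
      dalpha <- array(apply(dalphaFull, c(1, 2, 4), sum),
                      dim = c(dim(dsg)[1], dim(dsg)[2], 1, dim(dsg)[4]))
      dpsip <- dalpha * at$alpha * (1 - at$alpha)
      bw <- .conv2d_bw(at$a, w[[sprintf("dec%d_att_ps_W", j)]], dpsip)
      g[[sprintf("dec%d_att_ps_W", j)]] <- bw$dw
      g[[sprintf("dec%d_att_ps_b", j)]] <- bw$db
      da <- reluBw(at$ap, bw$dx)
      bw <- .conv2d_bw(dc$s, w[[sprintf("dec%d_att_th_W", j)]], da)
      g[[sprintf("dec%d_att_th_W", j)]] <- bw$dw
      g[[sprintf("dec%d_att_th_b", j)]] <- bw$db
      ds <- ds + bw$dx
      bw <- .conv2d_bw(at$gU, w[[sprintf("dec%d_att_ph_W", j)]], da)
      g[[sprintf("dec%d_att_ph_W", j)]] <- bw$dw
      g[[sprintf("dec%d_att_ph_b", j)]] <- bw$db
      dgAtt <- upsample2Bw(bw$dx)
    } else {
      ds <- dsg
    }
    si <- nE + 1L - j
    dskips[[si]] <- if (is.null(dskips[[si]])) ds else dskips[[si]] + ds

    dupp <- reluBw(dc$upp, du)
    bw <- .conv2d_bw(dc$up, w[[sprintf("dec%d_up_W", j)]], dupp)
    g[[sprintf("dec%d_up_W", j)]] <- bw$dw
    g[[sprintf("dec%d_up_b", j)]] <- bw$db
    dX <- upsample2Bw(bw$dx)
    if (!is.null(dgAtt)) dX <- dX + dgAtt
  }

  bt <- cache$bot
  db2 <- reluBw(bt$b2p, dX)
  bw <- .conv2d_bw(bt$be, w$bot_c2_W, db2)
  g$bot_c2_W <- bw$dw; g$bot_c2_b <- bw$db
  dbe <- bw$dx
  db1 <- if (cfg@useOSL) oslBw(bt$osl, dbe) else dbe
  db1 <- reluBw(bt$b1p, db1)
  bw <- .conv2d_bw(bt$xin, w$bot_c1_W, db1)
  g$bot_c1_W <- bw$dw; g$bot_c1_b <- bw$db
  dcur <- bw$dx

  for (i in rev(seq_len(nE))) {
    ec <- cache$enc[[i]]
    d <- dim(ec$a2)
    da2 <- .maxpool2_bw(dcur, ec$poolIdx, d[1], d[2])
    if (!is.null(dskips[[i]])) da2 <- da2 + dskips[[i]]
    da2 <- reluBw(ec$a2p, da2)
    bw <- .conv2d_bw(ec$a1, w[[sprintf("enc%d_c2_W", i)]], da2)
    g[[sprintf("enc%d_c2_W", i)]] <- bw$dw
    g[[sprintf("enc%d_c2_b", i)]] <- bw$db
    da1 <- reluBw(ec$a1p, bw$dx)
    bw <- .conv2d_bw(ec$xin, w[[sprintf("enc%d_c1_W", i)]], da1)
    g[[sprintf("enc%d_c1_W", i)]] <- bw$dw
    g[[sprintf("enc%d_c1_b", i)]] <- bw$db
    dcur <- bw$dx
  }
  g
}

#' Predict lesion probability maps
#'
#' Runs the network in evaluation mode (batch normalization uses running
#' estimates, dropout disabled) and returns per-pixel lesion
#' probabilities.
#'
#' @param model a [SegModel-class].
#' @param images `H x W x C` array (single image) or `H x W x C x N`
#'   batch, values in `[0, 1]`.
#' @param passes override for the number of feedback passes (defaults to
#'   the model configuration; ignored when feedback is disabled).
#' @return an `H x W x 1 x N` array of probabilities in `(0, 1)`.
#' @export
predictProb <- function(model, images, passes = NULL) {
  netForward(model, images, training = FALSE, passes = passes)$p
}
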