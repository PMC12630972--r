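test_that("encoder blocks produce the configured channels and halve dims", {
  cfg <- ModelConfig(encoderFilters = c(32L, 64L), bottleneckFilters = 128L,
                     inputSize = 64L)
  m <- buildModel(cfg, seed = 1)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  fw <- dermseg:::netForward(m, x)
  expect_equal(dim(fw$cache$enc[[1]]$a2), c(64, 64, 32, 1))
  expect_equal(dim(fw$cache$enc[[2]]$a2), c(32, 32, 64, 1))
  expect_equal(dim(fw$cache$enc[[2]]$xin), c(32, 32, 32, 1))  # pooled
  expect_equal(dim(fw$cache$bot$b1), c(16, 16, 128, 1))
  # OSL widens the bottleneck tensor by two channels
  expect_equal(dim(fw$cache$bot$be), c(16, 16, 130, 1))
  expect_error(dermseg:::netForward(m, array(0, c(63, 63, 3, 1))),
               "divisible")
  expect_error(dermseg:::netForward(m, array(0, c(64, 64, 4, 1))),
               "channels")
})

test_that("forward emits strictly interior probabilities, deterministically", {
  m <- buildModel(tinyConfig(), seed = 2)
  set.seed(42)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  p1 <- predictProb(m, x)
  p2 <- predictProb(m, x)
  expect_equal(dim(p1), c(32, 32, 1, 2))
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, p2)
  # attention coefficients lie in [0, 1]
  fw <- dermseg:::netForward(m, x)
  for (j in 1:2) {
    al <- fw$cache$dec[[j]]$att$alpha
    expect_true(all(al >= 0 & al <= 1))
  }
})

test_that("one feedback pass reduces exactly to the feedback-off forward", {
  m <- buildModel(tinyConfig(feedbackPasses = 3L), seed = 3)
  set.seed(43)
  for (trial in 1:10) {
    x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
    p1 <- predictProb(m, x, passes = 1)
    moff <- m
    moff@config@useFeedback <- FALSE
    poff <- predictProb(moff, x)
    expect_lt(max(abs(p1 - poff)), 1e-6)
    # extra passes refine rather than recompute: outputs differ
    pT <- predictProb(m, x)
    expect_gt(max(abs(pT - p1)), 0)
  }
})

test_that("parameter counts match the counting oracle across the ablation", {
  base <- list(useAttention = FALSE, useOSL = FALSE, useFeedback = FALSE)
  variants <- list(
    baseline = base,
    att = modifyList(base, list(useAttention = TRUE)),
    osl = modifyList(base, list(useOSL = TRUE)),
    fbk = modifyList(base, list(useFeedback = TRUE)),
    full = list(useAttention = TRUE, useOSL = TRUE, useFeedback = TRUE))
  counts <- vapply(variants, function(v) {
    cfg <- do.call(ModelConfig, c(list(encoderFilters = c(8L, 16L),
                                       bottleneckFilters = 32L,
                                       inputSize = 64L), v))
    m <- buildModel(cfg, seed = 1)
    expect_identical(nParams(m), as.integer(countParamsOracle(cfg)))
    nParams(m)
  }, integer(1))
  expect_true(all(counts["baseline"] <= counts))
  expect_true(all(counts <= counts["full"]))
  # enabling the OSL adds exactly 2 * kernel area * bottleneck filters
  expect_equal(counts[["osl"]] - counts[["baseline"]], 2L * 9L * 32L)
  # baseline truly carries no attention/OSL/feedback weights
  mb <- buildModel(do.call(ModelConfig, c(list(encoderFilters = c(8L, 16L),
                                               bottleneckFilters = 32L,
                                               inputSize = 64L), base)),
                   seed = 1)
  expect_false(any(grepl("att|fb", names(mb@weights))))
  expect_equal(dim(mb@weights$bot_c2_W)[3], 32)
})

test_that("backpropagation matches central finite differences", {
  cfg <- tinyConfig(useAttention = TRUE, useOSL = FALSE,
                    useFeedback = TRUE, feedbackPasses = 2L)
  m <- buildModel(cfg, seed = 7)
  # jitter biases away from zero so no ReLU pre-activation sits exactly
  # at the kink, where the numeric two-sided slope is ill-defined
  set.seed(11)
  for (nm in names(m@weights))
    m@weights[[nm]] <- m@weights[[nm]] + rnorm(length(m@weights[[nm]]),
                                               sd = 0.05)
  set.seed(1)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  y <- array((runif(32 * 32 * 2) > 0.6) * 1, c(32, 32, 1, 2))
  lossOf <- function(model) {
    fw <- dermseg:::netForward(model, x, training = TRUE, passes = 1)
    hybridLoss(fw$p, y)
  }
  fw <- dermseg:::netForward(m, x, training = TRUE, passes = 1)
  lg <- dermseg:::hybridLossGrad(fw$p, y, 0.5, 0.5)
  dz <- lg$dp * fw$p * (1 - fw$p)
  gr <- dermseg:::netBackward(m, fw$cache, dz)
  h <- 1e-5
  set.seed(99)
  rels <- c()
  for (nm in names(m@weights)) {
    if (grepl("fb", nm)) next   # zero feedback input on pass 1
    for (ii in sample(length(m@weights[[nm]]),
                      min(3, length(m@weights[[nm]])))) {
      mp <- m; mp@weights[[nm]][ii] <- mp@weights[[nm]][ii] + h
      mm <- m; mm@weights[[nm]][ii] <- mm@weights[[nm]][ii] - h
      num <- (lossOf(mp) - lossOf(mm)) / (2 * h)
      rels <- c(rels, abs(num - gr[[nm]][ii]) /
                  max(1e-7, abs(num) + abs(gr[[nm]][ii])))
    }
  }
  # individual finite differences can straddle ReLU kinks, so judge the
  # distribution: the bulk must agree tightly, no entry wildly off
  expect_lt(median(rels), 1e-5)
  expect_lt(max(rels), 0.1)
})

test_that("a single small optimization step decreases the sample loss", {
  cfg <- ModelConfig(encoderFilters = c(4L, 8L), bottleneckFilters = 16L,
                     inputSize = 64L, dropoutRate = 0)
  m <- buildModel(cfg, seed = 13)
  s <- dermseg:::sampleScene(64, 64, hair = NULL, lowContrastFrac = 0,
                             seed = 77)
  x <- array(s$image / 255, c(64, 64, 3, 1))
  y <- array(s$mask, c(64, 64, 1, 1))
  fw <- dermseg:::netForward(m, x, training = TRUE)
  lg <- dermseg:::hybridLossGrad(fw$p, y, 0.5, 0.5)
  dz <- lg$dp * fw$p * (1 - fw$p)
  gr <- dermseg:::netBackward(m, fw$cache, dz)
  for (nm in names(m@weights))
    m@weights[[nm]] <- m@weights[[nm]] - 0.05 * gr[[nm]]
  fw2 <- dermseg:::netForward(m, x, training = TRUE)
  expect_lt(hybridLoss(fw2$p, y), lg$loss)
})

test_that("spatial dims are conserved for any admissible input extent", {
  for (sz in c(32L, 48L, 64L)) {
    cfg <- tinyConfig()
    cfg@inputSize <- sz
    m <- buildModel(cfg, seed = 1)
    p <- predictProb(m, array(runif(sz * sz * 3), c(sz, sz, 3, 1)))
    expect_equal(dim(p)[1:2], c(sz, sz))
  }
})
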