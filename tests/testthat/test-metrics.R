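test_that("confusion counts match an exhaustive pixel loop", {
  set.seed(31)
  for (trial in 1:10) {
    pred <- matrix(rbinom(256, 1, 0.4), 16)
    truth <- matrix(rbinom(256, 1, 0.3), 16)
    cc <- confusionCounts(pred, truth)
    tp <- fp <- fn <- tn <- 0
    for (i in 1:16) for (j in 1:16) {
      if (pred[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1
      else if (pred[i, j] == 1) fp <- fp + 1
      else if (truth[i, j] == 1) fn <- fn + 1
      else tn <- tn + 1
    }
    expect_equal(unname(cc), c(tp, fp, fn, tn))
    expect_equal(sum(cc), 256)
  }
  pred <- matrix(0, 10, 10); pred[1:2, 1:5] <- 1
  expect_equal(unname(confusionCounts(pred, pred)), c(10L, 0L, 0L, 90L))
  expect_equal(unname(confusionCounts(matrix(1, 3, 3), matrix(0, 3, 3))),
               c(0L, 9L, 0L, 0L))
  expect_error(confusionCounts(pred, matrix(0, 3, 3)), "shapes differ")
})

test_that("dice and jaccard follow their set formulas and conventions", {
  a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
  expect_equal(diceCoef(a, a), 1)
  expect_equal(iouCoef(a, a), 1)
  b <- matrix(0, 4, 4); b[3:4, 3:4] <- 1
  expect_equal(diceCoef(a, b), 0)
  # |A| = 4, |B| = 6, overlap 3: dice 0.6, iou 3/7
  A <- matrix(0, 2, 5); A[1, 1:4] <- 1
  B <- matrix(0, 2, 5); B[1, 2:4] <- 1; B[2, 1:3] <- 1
  expect_equal(diceCoef(A, B), 0.6)
  expect_equal(iouCoef(A, B), 3 / 7)
  expect_equal(iouCoef(A, B), diceCoef(A, B) / (2 - diceCoef(A, B)))
  z <- matrix(0, 3, 3)
  expect_equal(diceCoef(z, z), 1)
  expect_equal(iouCoef(z, z), 1)
})

test_that("dice/jaccard identity, symmetry and bounds hold on random masks", {
  set.seed(32)
  for (trial in 1:200) {
    a <- matrix(rbinom(1024, 1, runif(1, 0.1, 0.9)), 32)
    b <- matrix(rbinom(1024, 1, runif(1, 0.1, 0.9)), 32)
    dc <- diceCoef(a, b); io <- iouCoef(a, b)
    expect_lt(abs(io - dc / (2 - dc)), 1e-12)
    expect_identical(dc, diceCoef(b, a))
    expect_identical(io, iouCoef(b, a))
    expect_true(io <= dc && dc <= 1 && io >= 0)
  }
})

test_that("pixel accuracy, precision and recall handle degenerate counts", {
  expect_equal(unname(basicRates(c(TP = 10, FP = 0, FN = 0, TN = 90))),
               c(1, 1, 1))
  r <- basicRates(c(TP = 3, FP = 3, FN = 1, TN = 93))
  expect_equal(unname(r), c(0.96, 0.5, 0.75))
  # all-negative prediction with empty truth: perfect by convention
  r0 <- basicRates(c(TP = 0, FP = 0, FN = 0, TN = 64))
  expect_equal(unname(r0), c(1, 1, 1))
  rbad <- basicRates(c(TP = 0, FP = 0, FN = 5, TN = 59))
  expect_equal(rbad[["precision"]], 0)
})

test_that("rank-based AUC equals the exhaustive threshold-sweep oracle", {
  expect_equal(rocAuc(c(0.9, 0.6, 0.4, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(rocAuc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_true(is.na(rocAuc(runif(5), rep(1, 5))))
  set.seed(33)
  for (trial in 1:50) {
    n <- sample(8:64, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2)   # coarse grid forces ties
    expect_equal(rocAuc(p, y), bruteAuc(p, y), tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(34)
  y <- rbinom(200, 1, 0.4)
  p <- plogis(rnorm(200) + y)
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE)))
  expect_equal(rocAuc(p, y), ref, tolerance = 1e-12)
})

test_that("hybrid loss behaves at its closed-form anchor points", {
  y <- array(rep(c(0, 1), each = 32), c(8, 8, 1, 1))
  # perfect prediction: loss ~ 0 (up to the soft-dice smoothing term)
  pPerfect <- array(pmin(pmax(y, 1e-7), 1 - 1e-7), dim(y))
  expect_lt(hybridLoss(pPerfect, y), 0.01)
  # BCE-only at p = 0.5 is ln 2 regardless of the truth split
  pHalf <- array(0.5, dim(y))
  expect_equal(hybridLoss(pHalf, y, wDice = 0, wBce = 1), log(2),
               tolerance = 1e-9)
  expect_gte(hybridLoss(pHalf, y), 0)
  expect_error(hybridLoss(pHalf, y, wDice = -1), "nonnegative")
  # moving probabilities toward the truth decreases the loss
  set.seed(35)
  p0 <- array(runif(64, 0.2, 0.8), dim(y))
  lprev <- hybridLoss(p0, y)
  for (step in 1:4) {
    p0 <- p0 + 0.2 * (y - p0)
    lnew <- hybridLoss(p0, y)
    expect_lt(lnew, lprev)
    lprev <- lnew
  }
})

test_that("evaluation aggregates per-image and pooled metrics correctly", {
  cfg <- tinyConfig()
  m <- buildModel(cfg, seed = 5)
  set.seed(36)
  imgs <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  msks <- array(rbinom(32 * 32 * 2, 1, 0.3), c(32, 32, 1, 2))
  rep <- evaluateModel(m, imgs, msks)
  expect_s4_class(rep, "MetricsReport")
  expect_true(rep@iou <= rep@dice)
  expect_equal(sum(rep@counts), 32 * 32 * 2)
  # hand aggregation on the same predictions
  p <- predictProb(m, imgs)
  pred <- (p > 0.5) * 1
  expect_equal(rep@dice, mean(c(diceCoef(pred[, , , 1], msks[, , , 1]),
                                diceCoef(pred[, , , 2], msks[, , , 2]))))
  expect_equal(rep@auc, rocAuc(p, msks))
  # duplicated image leaves per-image means unchanged
  rep2 <- evaluateModel(m, imgs[, , , c(1, 1), drop = FALSE],
                        msks[, , , c(1, 1), drop = FALSE])
  rep1 <- evaluateModel(m, imgs[, , , 1, drop = FALSE],
                        msks[, , , 1, drop = FALSE])
  expect_equal(rep2@dice, rep1@dice)
  expect_error(evaluateModel(m, imgs[, , , 0, drop = FALSE],
                             msks[, , , 0, drop = FALSE]))
})
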