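test_that("manifest splitting honors requested counts, seeded", {
  recs <- data.frame(image = sprintf("i%04d.png", 1:2594),
                     mask = sprintf("m%04d.png", 1:2594))
  sp <- splitManifest(recs, c(1815L, 259L, 520L), seed = 3)
  expect_equal(as.integer(table(sp$split)[c("train", "validation", "test")]),
               c(1815L, 259L, 520L))
  expect_equal(anyDuplicated(sp$image), 0L)
  # the 200-image supplementary split: 160 / 40 / 0
  recs2 <- data.frame(image = sprintf("p%03d.png", 1:200),
                      mask = sprintf("q%03d.png", 1:200))
  sp2 <- splitManifest(recs2, c(160L, 40L, 0L), seed = 1)
  expect_equal(sum(sp2$split == "train"), 160L)
  expect_equal(sum(sp2$split == "validation"), 40L)
  expect_equal(sum(sp2$split == "test"), 0L)
  expect_identical(splitManifest(recs2, c(160L, 40L, 0L), seed = 9),
                   splitManifest(recs2, c(160L, 40L, 0L), seed = 9))
  expect_error(splitManifest(recs2, c(300L, 0L, 0L)), "exceed")
})

test_that("plateau decay fires after exactly `patience` stalls", {
  st <- plateauState(lr = 1e-4)
  st <- plateauStep(st, 1)                  # baseline epoch sets best
  for (i in 1:9) st <- plateauStep(st, 1)   # 9 stalls: no decay yet
  expect_equal(st$lr, 1e-4)
  expect_equal(st$stall, 9L)
  st <- plateauStep(st, 0.5)                # improvement resets
  expect_equal(st$stall, 0L)
  expect_equal(st$lr, 1e-4)
  for (i in 1:10) st <- plateauStep(st, 1)  # 10 stalls: decay to 1e-5
  expect_equal(st$lr, 1e-5)
  expect_equal(st$stall, 0L)
  # strictly improving: untouched
  st2 <- plateauState(lr = 1e-4)
  for (l in seq(1, 0.1, by = -0.05)) st2 <- plateauStep(st2, l)
  expect_equal(st2$lr, 1e-4)
})

test_that("early stopping fires after exactly `patience` stalls", {
  st <- earlyStopState()
  st <- earlyStopStep(st, 1)                # baseline epoch sets best
  for (i in 1:14) st <- earlyStopStep(st, 1)
  expect_false(st$stop)
  st <- earlyStopStep(st, 0.5)              # improvement at stall 14
  expect_false(st$stop)
  expect_equal(st$stall, 0L)
  for (i in 1:15) st <- earlyStopStep(st, 1)
  expect_true(st$stop)
  st2 <- earlyStopState()
  for (l in seq(1, 0.05, by = -0.05)) st2 <- earlyStopStep(st2, l)
  expect_false(st2$stop)
})

test_that("scheduler counters match direct rule simulation on many patterns", {
  # exhaustive over all improve/stall patterns up to length 12, plus a
  # seeded sample of length-20 patterns (the state space repeats well
  # within that horizon)
  patterns <- list()
  for (L in 1:12)
    for (bits in 0:(2^L - 1))
      patterns[[length(patterns) + 1]] <-
        as.integer(intToBits(bits))[1:L] == 1
  set.seed(51)
  for (r in 1:2000)
    patterns[[length(patterns) + 1]] <- runif(20) < 0.5
  mismatches <- 0L
  for (pat in patterns) {
    pat <- c(TRUE, pat)   # baseline epoch establishes the running best
    losses <- lossesFromPattern(pat)
    orc <- oracleSchedule(pat)
    pl <- plateauState(lr = 1e-4, floor = 0)
    es <- earlyStopState()
    stopEpoch <- NA_integer_
    for (e in seq_along(losses)) {
      pl <- plateauStep(pl, losses[e])
      es <- earlyStopStep(es, losses[e])
      if (!identical(pl$lr, orc$lrs[e])) mismatches <- mismatches + 1L
      if (es$stop && is.na(stopEpoch)) stopEpoch <- e
    }
    if (!identical(stopEpoch, orc$stopEpoch)) mismatches <- mismatches + 1L
  }
  expect_identical(mismatches, 0L)
})

test_that("training on an easy task reduces the loss, reproducibly", {
  dat <- makeSceneData(12, size = 64, seedBase = 6000, hair = NULL,
                       lowContrastFrac = 0)
  val <- makeSceneData(4, size = 64, seedBase = 7000, hair = NULL,
                       lowContrastFrac = 0)
  cfg <- ModelConfig(encoderFilters = c(4L, 8L), bottleneckFilters = 16L,
                     inputSize = 64L, dropoutRate = 0)
  tc <- TrainConfig(batchSize = 4L, maxEpochs = 4L, seed = 2L, lr = 5e-4)
  fit1 <- trainModel(buildModel(cfg, 2), dat$images, dat$masks,
                     val$images, val$masks, tc)
  expect_lte(nrow(fit1$history), 4)
  expect_lt(fit1$history$train_loss[4], fit1$history$train_loss[1])
  expect_true(all(diff(fit1$history$epoch) == 1))
  # same seed, identical history (dropout off, no augmentation)
  fit2 <- trainModel(buildModel(cfg, 2), dat$images, dat$masks,
                     val$images, val$masks, tc)
  expect_identical(fit1$history, fit2$history)
  # restored best weights reproduce the recorded best validation loss
  best <- min(fit1$history$val_loss)
  vp <- dermseg:::validationPass(fit1$model, val$images, val$masks,
                                 0.5, 0.5)
  expect_equal(vp$loss, best, tolerance = 1e-12)
})

test_that("training defaults mirror the published protocol", {
  tc <- TrainConfig()
  expect_equal(tc@lr, 1e-4)
  expect_equal(c(tc@beta1, tc@beta2), c(0.9, 0.999))
  expect_equal(tc@batchSize, 16L)
  expect_equal(tc@maxEpochs, 150L)
  expect_equal(tc@lrFactor, 0.1)
  expect_equal(tc@lrPatience, 10L)
  expect_equal(tc@earlyStopPatience, 15L)
  cfg <- ModelConfig()
  expect_equal(cfg@encoderFilters, c(32L, 64L))
  expect_equal(cfg@bottleneckFilters, 128L)
  expect_equal(cfg@dropoutRate, 0.3)
  expect_equal(cfg@inputSize, 256L)
})
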