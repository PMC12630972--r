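test_that("black-hat matches the brute-force morphology oracle", {
  set.seed(101)
  for (trial in 1:10) {
    img <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32)
    for (k in c(5L, 17L)) {
      expect_identical(blackHat(img, c(k, k)), bruteBlackHat(img, k, k))
    }
  }
})

test_that("black-hat of a constant image is zero and responds to dark pits", {
  expect_true(all(blackHat(matrix(100, 40, 40), c(17, 17)) == 0))
  img <- matrix(100, 40, 40)
  img[20, 20] <- 0
  resp <- blackHat(img, c(17, 17))
  expect_equal(resp[20, 20], 100)
  # bright structures produce no response
  img2 <- matrix(100, 40, 40)
  img2[20, 5:35] <- 200
  resp2 <- blackHat(img2, c(17, 17))
  expect_true(all(resp2[20, 5:35] == 0))
  # nonnegativity on random inputs
  set.seed(7)
  r <- matrix(runif(900, 0, 255), 30)
  expect_true(all(blackHat(r, c(5, 5)) >= 0))
})

test_that("black-hat rejects bad kernels and non-grayscale input", {
  img <- matrix(0, 20, 20)
  expect_error(blackHat(img, c(4, 4)), "odd")
  expect_error(blackHat(img, c(21, 21)), "larger")
  expect_error(blackHat(array(0, c(8, 8, 3)), c(3, 3)), "grayscale")
})

test_that("hair-mask thresholding is strict at T and monotone in T", {
  resp <- matrix(c(51, 50, 0, 120), 2)
  m <- hairMask(resp, 50)
  expect_equal(m[1, 1], 255)  # response 51 > 50
  expect_equal(m[2, 1], 0)    # response 50 excluded (strict)
  expect_true(all(m %in% c(0, 255)))
  expect_true(all(hairMask(matrix(0, 4, 4), 50) == 0))
  set.seed(8)
  r <- matrix(runif(400, 0, 255), 20)
  low <- hairMask(r, 40); high <- hairMask(r, 90)
  expect_true(all(high <= low))  # raising T never adds pixels
  expect_error(hairMask(matrix(-1, 2, 2), 50))
})

test_that("inpainting is the identity outside the mask and fills lines", {
  img <- array(120, c(32, 32, 3))
  mask <- matrix(0, 32, 32)
  # empty mask: output identical
  expect_identical(inpaintHair(img, mask), img)
  # dark 1-px line reconstructed to within 2 units of the field
  mask[16, ] <- 1
  imgl <- img
  for (ch in 1:3) imgl[, , ch][mask == 1] <- 5
  out <- inpaintHair(imgl, mask * 255, 3)
  expect_true(all(abs(out[16, , ] - 120) <= 2))
  # unmasked pixels bit-exact
  for (ch in 1:3) expect_identical(out[, , ch][mask == 0],
                                   imgl[, , ch][mask == 0])
  expect_error(inpaintHair(img, matrix(1, 32, 32)), "whole image")
})

test_that("resize + normalization lands in [0,1] at the target extent", {
  img <- array(255, c(64, 64, 3))
  out <- resizeNormalize(img, 256)
  expect_equal(dim(out), c(256, 256, 3))
  expect_true(all(out == 1))
  expect_true(all(resizeNormalize(array(0, c(64, 64, 3)), 64) == 0))
  big <- array(sample(0:255, 512 * 512 * 3, TRUE), c(512, 512, 3))
  outb <- resizeNormalize(big, 256)
  expect_equal(dim(outb)[1:2], c(256L, 256L))
  expect_true(all(outb >= 0 & outb <= 1))
  expect_error(resizeNormalize(matrix(300, 64, 64)), "8-bit")
})

test_that("paired augmentation applies one transform to both members", {
  set.seed(9)
  img <- array(sample(0:255, 48 * 48 * 3, TRUE), c(48, 48, 3))
  mask <- matrix(0, 48, 48); mask[10:20, 15:30] <- 1

  idcfg <- augmentationConfig(0, 0, 0, 0, 0, FALSE, FALSE)
  a <- augmentPair(img, mask, idcfg, seed = 4)
  expect_equal(a$image, img, tolerance = 1e-12)
  expect_identical(a$mask, mask)

  # horizontal flip preserves foreground count exactly
  fcfg <- augmentationConfig(0, 0, 0, 0, 0, TRUE, FALSE)
  flipped <- NULL
  for (sd in 1:20) {
    af <- augmentPair(img, mask, fcfg, seed = sd)
    if (af$params$hflip) { flipped <- af; break }
  }
  expect_false(is.null(flipped))
  expect_equal(sum(flipped$mask), sum(mask))
  expect_identical(flipped$mask, mask[, ncol(mask):1])

  # default ranges are respected by the sampled parameters
  dcfg <- augmentationConfig()
  angles <- vapply(1:50, function(sd)
    augmentPair(img, mask, dcfg, seed = sd)$params$angle, numeric(1))
  expect_true(all(abs(angles) <= 30))

  # determinism: same seed, bit-identical outputs
  b1 <- augmentPair(img, mask, dcfg, seed = 11)
  b2 <- augmentPair(img, mask, dcfg, seed = 11)
  expect_identical(b1, b2)
  # masks stay binary after warping
  expect_true(all(b1$mask %in% c(0, 1)))
  expect_error(augmentPair(img, matrix(0, 10, 10), dcfg, 1), "differ")
})

test_that("pipeline composes hair removal, resize and mask handling", {
  img <- array(150, c(96, 96, 3))
  mask <- matrix(0, 96, 96); mask[30:60, 30:60] <- 1
  pp <- preprocessPipeline(img, mask, size = 64)
  expect_equal(dim(pp$image), c(64, 64, 3))
  expect_equal(dim(pp$mask), c(64, 64))
  expect_true(all(pp$mask %in% c(0, 1)))
  expect_true(sum(pp$mask) > 0)
  # constant (hairless) image passes through up to resize/normalize
  expect_true(all(abs(pp$image - 150 / 255) < 1e-12))
  expect_error(preprocessPipeline(array(0, c(32, 32, 3))), "64 x 64")

  # synthetic strands are detected at the default threshold
  s <- dermseg:::sampleScene(96, 96, hair = hairSpec(nStrands = 3),
                             lowContrastFrac = 0, seed = 41)
  pp2 <- preprocessPipeline(s$image, s$mask, size = 96)
  det <- pp2$hairMask > 0
  expect_gte(sum(det[s$hairTruth == 1]) / sum(s$hairTruth), 0.95)
})
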