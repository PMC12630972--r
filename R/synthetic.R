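# Seeded generator of synthetic dermoscopic-like scenes: a skin-tone
# background with a smooth illumination gradient and pixel noise, one
# irregular darker lesion with an exact ground-truth mask, and
# optional thin dark hair strands with their own truth mask. Defaults
# are chosen so the fixed hair-removal constants (17 x 17 element,
# threshold 50) operate in their intended regime: strands are 1-3 px
# wide and at least 80 intensity units darker than their surroundings.

#' Lesion shape/appearance specification
#'
#' @param center pixel coordinates `c(row, col)` of the lesion center.
#' @param semiAxes `c(a, b)` ellipse semi-axes in pixels (>= 4).
#' @param irregularity amplitude of the random low-order harmonic
#'   perturbation of the boundary radius, in `[0, 0.5]`.
#' @param contrast mean intensity offset of the lesion below the
#'   background, in 8-bit units (> 0; small values give the
#'   low-contrast regime).
#' @param textureSd intensity SD of the lesion texture noise.
#' @return a named list of class `LesionSpec`.
#' @export
lesionSpec <- function(center, semiAxes, irregularity = 0.2,
                       contrast = 60, textureSd = 3) {
  stopifnot(length(center) == 2, length(semiAxes) == 2,
            all(semiAxes >= 4), irregularity >= 0, irregularity <= 0.5,
            contrast > 0, textureSd >= 0)
  structure(list(center = center, semiAxes = semiAxes,
                 irregularity = irregularity, contrast = contrast,
                 textureSd = textureSd), class = "LesionSpec")
}

#' Hair occluder specification
#'
#' @param nStrands number of strands crossing the frame.
#' @param width strand width in pixels (1-3).
#' @param darkness intensity drop of the strand core below the scene
#'   (default 80, comfortably above the detection threshold of 50).
#' @param curvature control-point jitter as a fraction of the extent.
#' @return a named list of class `HairSpec`.
#' @export
hairSpec <- function(nStrands = 3L, width = 2, darkness = 80,
                     curvature = 0.15) {
  stopifnot(nStrands >= 0, width >= 1, width <= 3, darkness > 50,
            curvature >= 0)
  structure(list(nStrands = as.integer(nStrands), width = width,
                 darkness = darkness, curvature = curvature),
            class = "HairSpec")
}

#' Generate a skin-tone background
#'
#' Base color with a smooth low-frequency illumination gradient plus
#' per-pixel Gaussian noise, clipped to `[0, 255]`.
#'
#' @param h,w extent in pixels (>= 64).
#' @param seed integer seed (same seed, bit-identical output).
#' @param baseColor RGB base intensities.
#' @param gradientAmp peak-to-center amplitude of the illumination
#'   gradient (0 disables it).
#' @param noiseSd per-pixel noise SD (0 disables it).
#' @return `h x w x 3` 8-bit array.
#' @export
genBackground <- function(h, w, seed = 1L,
                          baseColor = c(205, 160, 140),
                          gradientAmp = 12, noiseSd = 3) {
  if (h < 64 || w < 64) stop("background must be at least 64 x 64")
  withSeed(seed, {
    rr <- matrix(seq(-1, 1, length.out = h), h, w)
    cc <- matrix(seq(-1, 1, length.out = w), h, w, byrow = TRUE)
    phi <- runif(1, 0, 2 * pi)
    grad <- gradientAmp * (cos(phi) * rr + sin(phi) * cc) / 2
    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      noise <- if (noiseSd > 0) matrix(rnorm(h * w, sd = noiseSd), h, w) else 0
      img[, , ch] <- baseColor[ch] + grad + noise
    }
    round(pmin(pmax(img, 0), 255))
  })
}

#' Generate an irregular lesion mask
#'
#' The boundary is an ellipse whose radius is modulated by a random
#' low-order harmonic series of relative amplitude `irregularity`; the
#' resulting star-shaped region is reduced to the single 4-connected
#' component containing the center.
#'
#' @param h,w frame extent in pixels.
#' @param spec a [lesionSpec()].
#' @param seed integer seed.
#' @return `h x w` binary matrix (single 4-connected component).
#' @export
genLesionMask <- function(h, w, spec, seed = 1L) {
  ctr <- spec$center; ax <- spec$semiAxes
  if (ctr[1] - ax[1] * 1.6 < 1 || ctr[1] + ax[1] * 1.6 > h ||
      ctr[2] - ax[2] * 1.6 < 1 || ctr[2] + ax[2] * 1.6 > w)
    stop("lesion does not fit in the frame with margin")
  withSeed(seed, {
    nHarm <- 4L
    amp <- runif(nHarm, 0, 1)
    amp <- if (sum(amp) > 0) amp / sum(amp) * spec$irregularity else amp
    phase <- runif(nHarm, 0, 2 * pi)
    rr <- matrix(seq_len(h), h, w) - ctr[1]
    cc <- matrix(seq_len(w), h, w, byrow = TRUE) - ctr[2]
    theta <- atan2(cc, rr)
    mod <- matrix(1, h, w)
    for (k in seq_len(nHarm))
      mod <- mod + amp[k] * cos((k + 1) * theta + phase[k])
    inside <- (rr / ax[1])^2 + (cc / ax[2])^2 <= mod^2
    keepComponent(inside * 1, round(ctr))
  })
}

# single 4-connected component containing the seed pixel, via
# vectorized flood fill (iterated dilation restricted to the mask)
keepComponent <- function(mask, seed) {
  h <- nrow(mask); w <- ncol(mask)
  comp <- matrix(0, h, w)
  if (mask[seed[1], seed[2]] == 0) return(comp)
  comp[seed[1], seed[2]] <- 1
  repeat {
    grown <- comp
    grown[-1, ] <- pmax(grown[-1, ], comp[-h, ])
    grown[-h, ] <- pmax(grown[-h, ], comp[-1, ])
    grown[, -1] <- pmax(grown[, -1], comp[, -w])
    grown[, -w] <- pmax(grown[, -w], comp[, -1])
    grown <- grown * mask
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

#' Render a lesion (and optional hairs) onto a background
#'
#' The lesion region is darkened by the spec's contrast with texture
#' noise and a 2-px feathered border; hairs are drawn as dark curved
#' strands of the given width over the whole frame (they may cross the
#' lesion; they are occluders, not lesion). The hair truth mask records
#' strand core pixels (coverage >= 3/4, where the full darkness
#' applies).
#'
#' @param background `h x w x 3` 8-bit array from [genBackground()].
#' @param mask binary lesion mask from [genLesionMask()].
#' @param spec the [lesionSpec()] used for contrast/texture.
#' @param hair optional [hairSpec()]; `NULL` for a hair-free scene.
#' @param seed integer seed.
#' @return list with `image` (8-bit array) and `hairTruth` (binary
#'   matrix, all-zero for hair-free scenes).
#' @export
renderScene <- function(background, mask, spec, hair = NULL, seed = 1L) {
  d <- dim(background)
  if (!identical(dim(mask), d[1:2])) stop("mask/background shape mismatch")
  h <- d[1]; w <- d[2]
  withSeed(seed, {
    # full darkening inside the lesion, smooth 2-px falloff outward
    feather <- pmax(mask, boxBlur(mask, 2L))
    img <- array(0, dim = d)
    tex <- if (spec$textureSd > 0)
      matrix(rnorm(h * w, sd = spec$textureSd), h, w) else 0
    drop <- feather * spec$contrast + mask * tex
    for (ch in 1:3) img[, , ch] <- background[, , ch] - drop

    hairTruth <- matrix(0, h, w)
    if (!is.null(hair) && hair$nStrands > 0) {
      cov <- matrix(0, h, w)
      for (s in seq_len(hair$nStrands)) {
        dist <- strandDistance(h, w, hair$curvature)
        half <- hair$width / 2
        cs <- pmin(pmax(half + 1 - dist, 0), 1)  # linear falloff, 1 px
        cov <- pmax(cov, cs)
      }
      hairTruth <- (cov >= 0.75) * 1
      for (ch in 1:3) img[, , ch] <- img[, , ch] - hair$darkness * cov
    }
    list(image = round(pmin(pmax(img, 0), 255)), hairTruth = hairTruth)
  })
}

# min distance to a random quadratic Bezier strand crossing the frame
strandDistance <- function(h, w, curvature) {
  side <- sample(2L, 1L)
  if (side == 1L) {  # left-right
    p0 <- c(runif(1, 1, h), 1)
    p2 <- c(runif(1, 1, h), w)
  } else {           # top-bottom
    p0 <- c(1, runif(1, 1, w))
    p2 <- c(h, runif(1, 1, w))
  }
  mid <- (p0 + p2) / 2 + c(runif(1, -curvature, curvature) * h,
                           runif(1, -curvature, curvature) * w)
  tt <- seq(0, 1, length.out = 2L * max(h, w))
  rs <- (1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * mid[1] + tt^2 * p2[1]
  cs <- (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * mid[2] + tt^2 * p2[2]
  .curve_distance(h, w, rs - 1, cs - 1, 4.0)
}

# normalized box blur with window (2r+1)^2, borders renormalized
boxBlur <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  run <- function(x, n, k) {
    cs <- rbind(0, apply(x, 2, cumsum))
    lo <- pmax(seq_len(n) - k, 0)
    hi <- pmin(seq_len(n) + k, n)
    (cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]) /
      (hi - lo)
  }
  t(run(t(run(m, h, r)), w, r))
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` PNG image/mask pairs (plus hair-truth masks when hairs are
#' enabled) with per-sample seeds derived from `seed`, and a manifest
#' CSV recording paths, split labels and seeds. A fraction of samples
#' (default 30%) is rendered in low-contrast mode with the lesion only
#' 15-30 intensity units darker than the background.
#'
#' @param n number of samples.
#' @param outDir output directory (created if needed).
#' @param size image extent in pixels.
#' @param hair a [hairSpec()] applied to every sample, or `NULL`.
#' @param lowContrastFrac fraction of low-contrast samples.
#' @param split optional character vector of length `n` with split
#'   labels recorded in the manifest.
#' @param seed master seed; the whole dataset is a pure function of the
#'   arguments.
#' @return the manifest as a data.frame (also written to
#'   `file.path(outDir, "manifest.csv")`).
#' @export
generateDataset <- function(n, outDir, size = 128L, hair = hairSpec(),
                            lowContrastFrac = 0.3, split = NULL,
                            seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    smp <- sampleScene(size, size, hair, lowContrastFrac,
                       seed = seed * 10000L + i)
    imgPath <- file.path(outDir, sprintf("img_%04d.png", i))
    mskPath <- file.path(outDir, sprintf("mask_%04d.png", i))
    writeImageFile(smp$image, imgPath)
    writeMaskFile(smp$mask * 255, mskPath)
    hairPath <- NA_character_
    if (!is.null(hair) && hair$nStrands > 0) {
      hairPath <- file.path(outDir, sprintf("hair_%04d.png", i))
      writeMaskFile(smp$hairTruth * 255, hairPath)
    }
    rows[[i]] <- data.frame(
      image = basename(imgPath), mask = basename(mskPath),
      hair = basename(hairPath),
      split = if (is.null(split)) NA_character_ else split[i],
      seed = seed * 10000L + i, lowContrast = smp$lowContrast)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  manifest
}

# one full scene with randomized lesion geometry (internal; also used
# by tests to build in-memory datasets without disk I/O)
sampleScene <- function(h, w, hair = NULL, lowContrastFrac = 0.3,
                        seed = 1L) {
  withSeed(seed, {
    low <- runif(1) < lowContrastFrac
    contrast <- if (low) runif(1, 15, 30) else runif(1, 45, 75)
    ax <- sort(runif(2, 0.14, 0.3) * min(h, w), decreasing = TRUE)
    ctr <- c(runif(1, 0.4, 0.6) * h, runif(1, 0.4, 0.6) * w)
    # pull the center in if the margin test would fail
    ctr[1] <- min(max(ctr[1], 1.6 * ax[1] + 1), h - 1.6 * ax[1] - 1)
    ctr[2] <- min(max(ctr[2], 1.6 * ax[2] + 1), w - 1.6 * ax[2] - 1)
    spec <- lesionSpec(center = ctr, semiAxes = ax,
                       irregularity = runif(1, 0.05, 0.3),
                       contrast = contrast, textureSd = 3)
    seeds <- sample.int(.Machine$integer.max, 3L)
    bg <- genBackground(h, w, seed = seeds[1])
    mask <- genLesionMask(h, w, spec, seed = seeds[2])
    sc <- renderScene(bg, mask, spec, hair = hair, seed = seeds[3])
    list(image = sc$image, mask = mask, hairTruth = sc$hairTruth,
         spec = spec, lowContrast = low)
  })
}
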