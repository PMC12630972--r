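# Hair-removal and input standardization pipeline: black-hat detection
# of dark thin structures, binary thresholding, fast-marching
# inpainting, resize to the network extent and [0,1] normalization,
# plus paired geometric augmentation.

#' Convert an RGB image to grayscale luminance
#'
#' Standard Rec. 601 luminance weighting (0.299 R + 0.587 G + 0.114 B).
#'
#' @param image `H x W x 3` numeric array.
#' @return `H x W` numeric matrix.
#' @export
rgbToGray <- function(image) {
  d <- dim(image)
  if (length(d) == 2L) return(image)
  if (length(d) != 3L || d[3] != 3L) stop("expected an H x W x 3 array")
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Black-hat transform
#'
#' Morphological closing (dilation then erosion with a rectangular
#' structuring element, windows clipped at the image border) minus the
#' input. The response is nonnegative everywhere and highlights dark
#' thin structures such as hairs; the default 17 x 17 element matches
#' the hair-detection pipeline.
#'
#' @param gray `H x W` grayscale intensity matrix.
#' @param kernel structuring element extent `c(height, width)`; both odd
#'   and >= 3.
#' @return `H x W` nonnegative response matrix.
#' @export
blackHat <- function(gray, kernel = c(17L, 17L)) {
  if (!is.matrix(gray)) stop("black-hat input must be a grayscale matrix")
  kh <- as.integer(kernel[1]); kw <- as.integer(kernel[2])
  if (kh < 3L || kw < 3L || kh %% 2L == 0L || kw %% 2L == 0L)
    stop("kernel dims must be odd and >= 3")
  if (kh > nrow(gray) || kw > ncol(gray))
    stop("structuring element larger than the image")
  closing <- .erode_rect(.dilate_rect(gray, kh, kw), kh, kw)
  closing - gray
}

#' Threshold a black-hat response into a hair mask
#'
#' Pixels with response strictly greater than `threshold` become 255,
#' all others 0.
#'
#' @param response nonnegative response matrix from [blackHat()].
#' @param threshold intensity threshold (default 50).
#' @return `H x W` matrix over {0, 255}.
#' @export
hairMask <- function(response, threshold = 50) {
  if (any(!is.finite(response)) || any(response < 0))
    stop("response must be finite and nonnegative")
  (response > threshold) * 255
}

#' Dilate a binary mask
#'
#' Binary dilation with a square (2r+1) x (2r+1) element. The
#' preprocessing pipeline dilates the thresholded hair mask by one
#' pixel before inpainting: strand edges fall below the detection
#' threshold but are still darkened, and leaving them as "known"
#' pixels would bias the reconstruction.
#'
#' @param mask `H x W` mask over {0, 255} or {0, 1}.
#' @param radius dilation radius in pixels.
#' @return mask of the same shape and coding ({0, 1}).
#' @export
dilateMask <- function(mask, radius = 1L) {
  m <- asBinary(mask)
  k <- 2L * as.integer(radius) + 1L
  (.dilate_rect(m, k, k) > 0) * 1
}

#' Inpaint masked pixels
#'
#' Reconstructs masked pixels by propagating intensity inward from the
#' mask boundary in fast-marching (distance) order; each pixel is the
#' inverse-square-distance weighted mean of already-known pixels within
#' `radius`. Unmasked pixels are returned bit-identical.
#'
#' @param image `H x W x 3` (or `H x W`) 8-bit intensity array.
#' @param mask `H x W` mask over {0, 255} or {0, 1}; nonzero = inpaint.
#' @param radius neighborhood radius in pixels (>= 1).
#' @return array of the same shape, 8-bit values.
#' @export
inpaintHair <- function(image, mask, radius = 3L) {
  d <- dim(image)
  if (is.null(d)) stop("image must be an array")
  m <- asBinary(mask)
  if (!identical(dim(m)[1:2], d[1:2])) stop("mask/image shape mismatch")
  if (all(m == 1)) stop("mask covers the whole image; nothing to propagate from")
  storage.mode(image) <- "double"
  out <- .inpaint_fmm(image, matrix(as.integer(m), nrow = d[1]),
                      as.integer(radius))
  round(pmin(pmax(out, 0), 255))
}

#' Resize to the network extent and normalize to \[0, 1\]
#'
#' Bilinear resampling to `size x size`, then division of the 8-bit
#' values by 255.
#'
#' @param image `H x W x 3` (or `H x W`) 8-bit array.
#' @param size output extent in pixels (default 256).
#' @return `size x size (x 3)` array with values in `[0, 1]`.
#' @export
resizeNormalize <- function(image, size = 256L) {
  d <- dim(image)
  if (is.null(d) || any(d[1:2] < 1)) stop("degenerate input image")
  if (any(image < 0) || any(image > 255)) stop("expected 8-bit intensities")
  out <- EBImage::resize(image, w = size, h = size, filter = "bilinear")
  as.array(out) / 255
}

# nearest-neighbor mask resize + re-binarization at 0.5
resizeMask <- function(mask, size = 256L) {
  m <- asBinary(mask)
  out <- as.array(EBImage::resize(m, w = size, h = size, filter = "none"))
  (out > 0.5) * 1
}

#' Augmentation configuration
#'
#' Ranges follow the published protocol: rotations within +/- 30
#' degrees, horizontal/vertical shifts within 10% of the extent, shear
#' factor within +/- 0.2, zoom up to 40% (scale factor in
#' `[1 - zoom, 1 + zoom]`), and random horizontal and vertical flips.
#'
#' @param rotation max absolute rotation, degrees.
#' @param widthShift,heightShift max absolute shift, fraction of extent.
#' @param shear max absolute shear factor.
#' @param zoom max relative zoom deviation.
#' @param horizontalFlip,verticalFlip enable random flips.
#' @return a named list of class `AugmentationConfig`.
#' @export
augmentationConfig <- function(rotation = 30, widthShift = 0.10,
                               heightShift = 0.10, shear = 0.2,
                               zoom = 0.40, horizontalFlip = TRUE,
                               verticalFlip = TRUE) {
  stopifnot(rotation >= 0, widthShift >= 0, widthShift < 1,
            heightShift >= 0, heightShift < 1, shear >= 0, zoom >= 0)
  structure(list(rotation = rotation, widthShift = widthShift,
                 heightShift = heightShift, shear = shear, zoom = zoom,
                 horizontalFlip = isTRUE(horizontalFlip),
                 verticalFlip = isTRUE(verticalFlip)),
            class = "AugmentationConfig")
}

#' Apply one random geometric transform to an image/mask pair
#'
#' A single affine transform (rotation, shift, shear, zoom, flips) with
#' parameters drawn uniformly within the configured ranges from the
#' seeded stream is applied identically to both inputs. The image is
#' interpolated bilinearly with reflected borders; the mask uses
#' nearest-neighbor sampling with zero fill and is re-binarized, so no
#' phantom lesion pixels can appear.
#'
#' @param image `H x W x C` (or `H x W`) numeric array.
#' @param mask `H x W` binary mask aligned with the image (or `NULL`).
#' @param config an [augmentationConfig()].
#' @param seed integer seed; identical seeds give identical transforms.
#' @return list with `image`, `mask` and the sampled `params`.
#' @export
augmentPair <- function(image, mask = NULL, config = augmentationConfig(),
                        seed = 1L) {
  d <- dim(image)
  if (!is.null(mask) && !identical(dim(mask)[1:2], d[1:2]))
    stop("image and mask shapes differ")
  pars <- withSeed(seed, list(
    angle = runif(1, -config$rotation, config$rotation),
    shiftR = runif(1, -config$heightShift, config$heightShift) * d[1],
    shiftC = runif(1, -config$widthShift, config$widthShift) * d[2],
    shear = runif(1, -config$shear, config$shear),
    zoom = runif(1, 1 - config$zoom, 1 + config$zoom),
    hflip = config$horizontalFlip && runif(1) < 0.5,
    vflip = config$verticalFlip && runif(1) < 0.5
  ))
  m <- affineCoeffs(d[1], d[2], pars)
  img2 <- .affine_warp(as4dImage(image), m, TRUE, 1L, 0)
  img2 <- array(img2, dim = d)
  msk2 <- NULL
  if (!is.null(mask)) {
    mm <- asBinary(mask)
    msk2 <- .affine_warp(as4dImage(mm), m, FALSE, 0L, 0)
    msk2 <- (array(msk2, dim = dim(mm)) > 0.5) * 1
  }
  list(image = img2, mask = msk2, params = pars)
}

as4dImage <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) dim(x) <- c(d, 1L)
  storage.mode(x) <- "double"
  x
}

# Inverse affine map coefficients for .affine_warp: output (r, c) ->
# source (r, c), composing zoom, shear, rotation, flips and shift about
# the image center.
affineCoeffs <- function(H, W, pars) {
  th <- pars$angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- matrix(c(1, 0, pars$shear, 1), 2, 2)       # shear along columns
  Z <- diag(c(pars$zoom, pars$zoom))
  Fl <- diag(c(if (pars$vflip) -1 else 1, if (pars$hflip) -1 else 1))
  A <- Fl %*% R %*% S %*% Z
  Ainv <- solve(A)
  ctr <- c((H - 1) / 2, (W - 1) / 2)
  shift <- c(pars$shiftR, pars$shiftC)
  # forward: out = A (in - ctr) + ctr + shift  =>
  # in = Ainv (out - ctr - shift) + ctr
  off <- -Ainv %*% (ctr + shift) + ctr
  c(Ainv[1, 1], Ainv[1, 2], off[1], Ainv[2, 1], Ainv[2, 2], off[2])
}

#' Full preprocessing pipeline
#'
#' Grayscale conversion, black-hat hair detection, thresholding,
#' inpainting (all at native resolution, before any resizing so thin
#' strands are not lost to downsampling), then resize and normalization.
#' A paired mask, when given, is resized with nearest-neighbor sampling
#' and re-binarized; it is never inpainted.
#'
#' @param image `H x W x 3` 8-bit array, `H, W >= 64`.
#' @param mask optional `H x W` binary lesion mask.
#' @param kernel,threshold,radius hair-detection parameters (17 x 17
#'   element, threshold 50, inpaint radius 3 by default).
#' @param doHairRemoval disable to skip detection/inpainting.
#' @param size output extent (default 256).
#' @return list with `image` (`size x size x 3`, in `[0, 1]`), `mask`
#'   (`size x size` binary or `NULL`) and `hairMask` (native-resolution
#'   {0, 255} matrix, or `NULL` when hair removal is off).
#' @export
preprocessPipeline <- function(image, mask = NULL,
                               kernel = c(17L, 17L), threshold = 50,
                               radius = 3L, doHairRemoval = TRUE,
                               size = 256L) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("expected an H x W x 3 image")
  if (d[1] < 64 || d[2] < 64) stop("image must be at least 64 x 64")
  hm <- NULL
  if (doHairRemoval) {
    gray <- rgbToGray(image)
    resp <- blackHat(gray, kernel)
    hm <- hairMask(resp, threshold)
    if (any(hm > 0)) image <- inpaintHair(image, dilateMask(hm, 1L), radius)
  }
  out <- resizeNormalize(image, size)
  mk <- if (!is.null(mask)) resizeMask(mask, size) else NULL
  list(image = out, mask = mk, hairMask = hm)
}
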