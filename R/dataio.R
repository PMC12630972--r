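# Readers/writers for the standard on-disk formats: PNG/JPEG images,
# single-channel {0,255} PNG masks, CSV manifests, YAML/JSON run
# configurations.

#' Load and validate a dataset manifest
#'
#' The manifest is a CSV with header columns `image` and `mask`
#' (optionally `split`, `hair`, `seed`, ...). Paths are resolved
#' relative to `baseDir` and checked for existence; problems are
#' reported with their row numbers.
#'
#' @param path manifest CSV path.
#' @param baseDir directory paths are resolved against (defaults to the
#'   manifest's directory).
#' @param checkFiles verify that referenced files exist.
#' @return data.frame of validated records with absolute `image` and
#'   `mask` paths.
#' @export
loadManifest <- function(path, baseDir = dirname(path),
                         checkFiles = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed manifest CSV: ",
                                          conditionMessage(e)))
  if (nrow(df) == 0) stop("empty manifest: ", path)
  missing <- setdiff(c("image", "mask"), names(df))
  if (length(missing))
    stop("manifest lacks required column(s): ",
         paste(missing, collapse = ", "))
  resolve <- function(p) ifelse(is.na(p) | p == "" | grepl("^/", p),
                                p, file.path(baseDir, p))
  df$image <- resolve(df$image)
  df$mask <- resolve(df$mask)
  if ("hair" %in% names(df)) df$hair <- resolve(df$hair)
  if (checkFiles) {
    for (col in c("image", "mask")) {
      bad <- which(!is.na(df[[col]]) & !file.exists(df[[col]]))
      if (length(bad))
        stop("manifest row(s) ", paste(bad, collapse = ", "),
             ": missing ", col, " file(s), e.g. ", df[[col]][bad[1]])
    }
  }
  df
}

#' Read an image file as an 8-bit array
#'
#' PNG and JPEG are supported. 16-bit PNG input is rescaled to 8 bits
#' with a warning. Grayscale input is returned as a matrix; color input
#' as `H x W x 3` (any alpha channel is dropped).
#'
#' @param path file path.
#' @return numeric array of 8-bit intensities (0-255).
#' @export
readImageFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "jpg", "jpeg"))
    stop("unsupported image format: .", ext)
  if (!file.exists(path)) stop("file not found: ", path)
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    info <- attr(raw, "info")
    if (!is.null(info$bit.depth) && info$bit.depth > 8)
      warning("16-bit PNG rescaled to 8-bit: ", path)
    attr(raw, "info") <- NULL
    x <- round(raw * 255)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop("the jpeg package is required to read JPEG files")
    x <- round(jpeg::readJPEG(path) * 255)
  } else {
    stop("unsupported image format: .", ext)
  }
  d <- dim(x)
  if (length(d) == 3L && d[3] > 3L) x <- x[, , 1:3]
  if (length(d) == 3L && dim(x)[3] == 1L) x <- x[, , 1]
  x
}

#' Read / write binary masks
#'
#' Masks are single-channel PNGs over {0, 255}. Writing then reading a
#' mask is bit-exact.
#'
#' @param mask `H x W` matrix over {0, 255} (or {0, 1}, rescaled).
#' @param path file path.
#' @return `readMaskFile`: `H x W` matrix over {0, 255}.
#' @export
writeMaskFile <- function(mask, path) {
  m <- asBinary(mask)
  png::writePNG(m, path)
  invisible(path)
}

#' @rdname writeMaskFile
#' @export
readMaskFile <- function(path) {
  x <- readImageFile(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  u <- unique(as.vector(x))
  if (!all(u %in% c(0, 255)))
    stop("mask file is not binary {0,255}: ", path)
  x
}

# write an 8-bit RGB or grayscale image as PNG
writeImageFile <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' Nested sections (`preprocess`, `model`, `training`, `evaluation`)
#' mirror the package's parameter objects; unknown top-level keys are
#' rejected so typos fail loudly.
#'
#' @param path configuration file (`.yaml`, `.yml` or `.json`).
#' @return named list of configuration sections.
#' @export
loadRunConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported config format: .", ext)
  allowed <- c("schema_version", "preprocess", "model", "training",
               "evaluation", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg
}

# load an image/mask set from manifest records into in-memory arrays
loadRecords <- function(records, size = NULL) {
  n <- nrow(records)
  first <- readImageFile(records$image[1])
  if (is.null(size)) size <- nrow(first)
  images <- array(0, dim = c(size, size, 3, n))
  masks <- array(0, dim = c(size, size, 1, n))
  for (i in seq_len(n)) {
    img <- readImageFile(records$image[i])
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    msk <- readMaskFile(records$mask[i])
    if (nrow(img) != size)
      images[, , , i] <- resizeNormalize(img, size)
    else images[, , , i] <- img / 255
    masks[, , 1, i] <- if (nrow(msk) != size) resizeMask(msk, size)
                       else asBinary(msk)
  }
  list(images = images, masks = masks)
}
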