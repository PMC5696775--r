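#' Read an RGB image
#'
#' Loads a PNG, JPEG or TIFF raster and returns a height x width x 3 numeric
#' array of intensities normalized to \[0, 1\] by the source bit-depth maximum
#' (255 for 8-bit, 65535 for 16-bit containers; 12-bit camera data is usually
#' delivered in 16-bit containers and is normalized accordingly). Greyscale
#' sources are replicated across the three channels.
#'
#' @param path Path to an image file (`.png`, `.jpg`, `.jpeg`, `.tif`,
#'   `.tiff`).
#' @return A numeric array with `dim = c(height, width, 3)`, channels in
#'   R, G, B order, all values in \[0, 1\].
#' @seealso [read_mask()], [write_mask()]
#' @export
#' @examples
#' p <- tempfile(fileext = ".png")
#' png::writePNG(array(runif(12), dim = c(2, 2, 3)), p)
#' img <- read_image(p)
#' dim(img)
read_image <- function(path) {
  x <- read_raster(path)
  if (length(dim(x)) == 2L) {
    x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  } else if (dim(x)[3L] == 1L) {
    x <- array(rep(x[, , 1L], 3L), dim = c(dim(x)[1:2], 3L))
  } else if (dim(x)[3L] != 3L) {
    stop("unsupported channel count (", dim(x)[3L], ") in '", path,
         "': expected a 1- or 3-channel raster", call. = FALSE)
  }
  storage.mode(x) <- "double"
  validate_image(x)
  x
}

# decode by extension; readers return values already scaled to [0,1]
read_raster <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read image: file '", path, "' does not exist", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  x <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      jpg  = ,
      jpeg = jpeg::readJPEG(path),
      tif  = ,
      tiff = tiff::readTIFF(path),
      stop("unsupported image format '.", ext, "'", call. = FALSE)
    ),
    error = function(e) {
      stop("failed to decode '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  x
}

#' Read a binary segmentation mask
#'
#' Loads a single-channel image holding at most two distinct values and
#' returns a logical matrix, `TRUE` for plant (values above half of full
#' scale) and `FALSE` for background.
#'
#' @param path Path to a single-channel PNG/TIFF mask image.
#' @return A logical matrix of the image's dimensions.
#' @export
read_mask <- function(path) {
  x <- read_raster(path)
  if (length(dim(x)) == 3L) {
    if (dim(x)[3L] == 1L) {
      x <- x[, , 1L]
    } else {
      flat <- all(x[, , 1L] == x[, , 2L]) && all(x[, , 1L] == x[, , 3L])
      if (!flat) {
        stop("'", path, "' has multiple unequal channels; ",
             "not a single-channel binary mask", call. = FALSE)
      }
      x <- x[, , 1L]
    }
  }
  vals <- unique(as.vector(x))
  if (length(vals) > 2L) {
    stop("'", path, "' holds ", length(vals),
         " distinct values; it does not look like a binary mask",
         call. = FALSE)
  }
  x > 0.5
}

#' Write a binary mask to an 8-bit PNG
#'
#' Serializes a logical plant/background matrix as a single-channel 8-bit PNG
#' with plant = 255 and background = 0, so that
#' `read_mask(write_mask(m, p))` reproduces `m` exactly.
#'
#' @param mask A logical matrix (`TRUE` = plant).
#' @param path Output file path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  validate_mask(mask)
  if (!dir.exists(dirname(path))) {
    stop("cannot write mask: directory '", dirname(path),
         "' does not exist", call. = FALSE)
  }
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

validate_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] != 3L) {
    stop("image must be a height x width x 3 numeric array", call. = FALSE)
  }
  if (dim(image)[1L] < 1L || dim(image)[2L] < 1L) {
    stop("image must have positive height and width", call. = FALSE)
  }
  if (anyNA(image) || min(image) < 0 || max(image) > 1) {
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  }
  invisible(image)
}

validate_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("mask must be a logical matrix (TRUE = plant)", call. = FALSE)
  }
  if (anyNA(mask)) stop("mask must not contain NA", call. = FALSE)
  invisible(mask)
}

# flatten an image to an N x 3 matrix in row-major pixel order:
# row i (1-based) is pixel ((i-1) %/% width, (i-1) %% width), origin top-left
flatten_rgb <- function(image) {
  cbind(as.vector(t(image[, , 1L])),
        as.vector(t(image[, , 2L])),
        as.vector(t(image[, , 3L])))
}

# inverse of flatten_rgb for a single per-pixel value vector
unflatten <- function(values, height, width) {
  t(matrix(values, nrow = width, ncol = height))
}
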