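# Colour-index and clustering baselines: ExG, ExGR, CIVE and K-means in
# L*u*v* space, with Otsu or fixed positive thresholding.

index_map <- function(values, name) {
  attr(values, "index_name") <- name
  values
}

# channel as a matrix even for 1x1 images
chan <- function(image, k) {
  matrix(image[, , k], dim(image)[1L], dim(image)[2L])
}

#' Excess Green index (ExG)
#'
#' Per-pixel `2G - R - B`. Green vegetation scores high, soil near zero.
#'
#' @param image A height x width x 3 array in \[0,1\].
#' @return A height x width numeric matrix (attribute `index_name = "ExG"`).
#' @export
exg <- function(image) {
  validate_image(image)
  index_map(2 * chan(image, 2) - chan(image, 1) - chan(image, 3), "ExG")
}

#' Excess Green minus Excess Red index (ExGR)
#'
#' Per-pixel `ExG - (1.4 R - G) = 3G - 2.4R - B`. Designed to be positive on
#' vegetation, so it is segmented with a fixed threshold at zero.
#'
#' @inheritParams exg
#' @return A height x width numeric matrix (attribute `index_name = "ExGR"`).
#' @export
exgr <- function(image) {
  validate_image(image)
  index_map(3 * chan(image, 2) - 2.4 * chan(image, 1) - chan(image, 3),
            "ExGR")
}

#' Colour Index of Vegetation Extraction (CIVE)
#'
#' Per-pixel `0.441 R - 0.811 G + 0.385 B + 18.78745` with R, G, B the
#' \[0,1\] channels and the additive constant kept as conventionally printed.
#' Greener pixels score lower (negative green coefficient).
#'
#' @inheritParams exg
#' @return A height x width numeric matrix (attribute `index_name = "CIVE"`).
#' @export
cive <- function(image) {
  validate_image(image)
  index_map(0.441 * chan(image, 1) - 0.811 * chan(image, 2) +
              0.385 * chan(image, 3) + 18.78745, "CIVE")
}

#' Otsu's automatic threshold for a real-valued index map
#'
#' Bins the index values into a 256-bin histogram spanning their observed
#' range and returns the bin edge maximizing the between-class variance;
#' ties are broken by the lowest such edge. Classes are "value <= edge"
#' versus "value > edge".
#'
#' @param index A numeric matrix or vector of finite index values with at
#'   least two distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @return The scalar threshold.
#' @export
otsu_threshold <- function(index, n_bins = 256L) {
  x <- as.vector(index)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("index map must be finite", call. = FALSE)
  }
  rng <- range(x)
  if (rng[1L] == rng[2L]) {
    stop("index map is constant: Otsu thresholding is undefined ",
         "(no bimodality to separate)", call. = FALSE)
  }
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  p <- counts / length(x)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)[-n_bins]
  m0 <- cumsum(p * mids)[-n_bins]
  mT <- sum(p * mids)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins - 1L)
  sigma_b[valid] <- (mT * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  t_star <- which.max(sigma_b)  # first maximum = lowest tied threshold
  edges[t_star + 1L]
}

#' Segment vegetation with ExG + Otsu thresholding
#'
#' Plant wherever the ExG index exceeds its Otsu threshold.
#'
#' @inheritParams exg
#' @return A logical plant/background matrix.
#' @export
segment_exg <- function(image) {
  idx <- exg(image)
  idx > otsu_threshold(idx)
}

#' Segment vegetation with ExGR + fixed positive threshold
#'
#' Plant wherever the ExGR index is strictly positive.
#'
#' @inheritParams exg
#' @return A logical plant/background matrix.
#' @export
segment_exgr <- function(image) {
  exgr(image) > 0
}

#' Segment vegetation with CIVE + Otsu thresholding
#'
#' Plant wherever the CIVE index falls strictly below its Otsu threshold:
#' the green coefficient of CIVE is negative, so vegetation occupies the
#' low mode of the index histogram.
#'
#' @inheritParams exg
#' @return A logical plant/background matrix.
#' @export
segment_cive <- function(image) {
  idx <- cive(image)
  idx < otsu_threshold(idx)
}

#' Segment vegetation by K-means clustering in L*u*v* space
#'
#' Clusters the per-pixel (L*, u*, v*) coordinates into `k` clusters and
#' labels a pixel as plant iff its cluster centre has `u* < 0` and `v* > 0`
#' (strict inequalities) — the region of colour space where greens fall.
#' If the image holds no more than `k` distinct colours, each distinct
#' colour becomes its own cluster centre exactly; otherwise a seeded
#' multi-start Hartigan-Wong K-means is run.
#'
#' @inheritParams exg
#' @param k Number of clusters (default 20).
#' @param seed Integer seed making the clustering reproducible.
#' @param nstart Number of random starts (default 5).
#' @return A logical plant/background matrix.
#' @export
kmeans_segment <- function(image, k = 20L, seed = 0L, nstart = 5L) {
  validate_image(image)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (h * w < k) {
    stop("image has ", h * w, " pixels, fewer than k = ", k, call. = FALSE)
  }
  luv <- rgb_to_luv(flatten_rgb(image))
  key <- paste(luv[, 1L], luv[, 2L], luv[, 3L])
  ukey <- unique(key)
  if (length(ukey) <= k) {
    centres <- luv[match(ukey, key), , drop = FALSE]
    assign <- match(key, ukey)
  } else {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    km <- suppressWarnings(
      stats::kmeans(luv, centers = k, nstart = nstart, iter.max = 100L)
    )
    centres <- km$centers
    assign <- km$cluster
  }
  plant_cluster <- centres[, 2L] < 0 & centres[, 3L] > 0
  unflatten(plant_cluster[assign], h, w)
}
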