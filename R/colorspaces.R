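# Colour-space conversions used for per-pixel feature extraction.
#
# Conventions (fixed so that independent implementations can agree):
#   * All transforms act directly on the [0,1] R,G,B values as stored, with
#     no sRGB linearization step.
#   * CIE L*a*b* and L*u*v* use the sRGB primaries -> XYZ matrix and the D65
#     reference white.
#   * Hue channels (HSV and HSI) are scaled to [0, 1); achromatic pixels get
#     hue 0 and saturation 0 by convention.
#   * YCbCr uses BT.601 luma with full-range chroma offset at 0.5; YUV uses
#     BT.601 luma with the analog U/V scalings, so the two chroma pairs are
#     genuinely distinct features.

# sRGB -> XYZ (D65)
RGB2XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3L, byrow = TRUE)

# reference white = matrix row sums, so R=G=B maps to exactly zero chroma
WHITE_D65 <- c(X = sum(RGB2XYZ[1, ]), Y = sum(RGB2XYZ[2, ]),
               Z = sum(RGB2XYZ[3, ]))

rgb_to_xyz <- function(rgb) rgb %*% t(RGB2XYZ)

lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

rgb_to_lab <- function(rgb) {
  xyz <- rgb_to_xyz(rgb)
  fx <- lab_f(xyz[, 1L] / WHITE_D65[["X"]])
  fy <- lab_f(xyz[, 2L] / WHITE_D65[["Y"]])
  fz <- lab_f(xyz[, 3L] / WHITE_D65[["Z"]])
  cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

rgb_to_luv <- function(rgb) {
  xyz <- rgb_to_xyz(rgb)
  X <- xyz[, 1L]; Y <- xyz[, 2L]; Z <- xyz[, 3L]
  L <- 116 * lab_f(Y / WHITE_D65[["Y"]]) - 16
  den <- X + 15 * Y + 3 * Z
  dn <- WHITE_D65[["X"]] + 15 * WHITE_D65[["Y"]] + 3 * WHITE_D65[["Z"]]
  up_n <- 4 * WHITE_D65[["X"]] / dn
  vp_n <- 9 * WHITE_D65[["Y"]] / dn
  up <- ifelse(den > 0, 4 * X / den, up_n)   # black: zero chroma
  vp <- ifelse(den > 0, 9 * Y / den, vp_n)
  cbind(L = L, u = 13 * L * (up - up_n), v = 13 * L * (vp - vp_n))
}

# standard hexcone model, hue on [0, 1)
rgb_to_hsv <- function(rgb) {
  r <- rgb[, 1L]; g <- rgb[, 2L]; b <- rgb[, 3L]
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  c_ <- mx - mn
  h <- numeric(length(r))
  i <- c_ > 0 & mx == r
  h[i] <- ((g[i] - b[i]) / c_[i]) %% 6
  i <- c_ > 0 & mx == g & mx != r
  h[i] <- (b[i] - r[i]) / c_[i] + 2
  i <- c_ > 0 & mx == b & mx != r & mx != g
  h[i] <- (r[i] - g[i]) / c_[i] + 4
  h <- h / 6
  s <- ifelse(mx > 0, c_ / mx, 0)
  cbind(H = h, S = s, V = mx)
}

# inverse hexcone; used by the synthetic-scene renderer and round-trip tests
hsv_to_rgb <- function(hsv) {
  h <- (hsv[, 1L] %% 1) * 6
  s <- hsv[, 2L]; v <- hsv[, 3L]
  c_ <- v * s
  x <- c_ * (1 - abs(h %% 2 - 1))
  m <- v - c_
  k <- floor(h) %% 6
  r <- ifelse(k == 0 | k == 5, c_, ifelse(k == 1 | k == 4, x, 0))
  g <- ifelse(k == 0 | k == 3, x, ifelse(k == 1 | k == 2, c_, 0))
  b <- ifelse(k == 2 | k == 5, x, ifelse(k == 3 | k == 4, c_, 0))
  cbind(R = r + m, G = g + m, B = b + m)
}

# classical arccos-based HSI; hue on [0, 1), 0 when undefined
rgb_to_hsi <- function(rgb) {
  r <- rgb[, 1L]; g <- rgb[, 2L]; b <- rgb[, 3L]
  total <- r + g + b
  i <- total / 3
  s <- ifelse(total > 0, 1 - 3 * pmin(r, g, b) / total, 0)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  theta <- acos(pmin(pmax(ifelse(den > 0, num / den, 0), -1), 1))
  h <- ifelse(den > 0, ifelse(b > g, 2 * pi - theta, theta) / (2 * pi), 0)
  cbind(H = h, S = s, I = i)
}

# BT.601 luma; full-range chroma centred at 0.5
rgb_to_ycbcr <- function(rgb) {
  r <- rgb[, 1L]; g <- rgb[, 2L]; b <- rgb[, 3L]
  y <- 0.299 * r + 0.587 * g + 0.114 * b
  cbind(Y = y,
        Cb = 0.5 + (b - y) / 1.772,
        Cr = 0.5 + (r - y) / 1.402)
}

# BT.601 luma with analog U/V scalings
rgb_to_yuv <- function(rgb) {
  r <- rgb[, 1L]; g <- rgb[, 2L]; b <- rgb[, 3L]
  y <- 0.299 * r + 0.587 * g + 0.114 * b
  cbind(Y = y, U = 0.492 * (b - y), V = 0.877 * (r - y))
}

COLOR_SPACES <- c("LAB", "LUV", "HSV", "HSI", "YCBCR", "YUV")

#' Convert an RGB image to another colour space
#'
#' Applies a deterministic per-pixel transform to one of the six colour
#' spaces used by the multi-feature representation. Transforms act directly
#' on the stored \[0,1\] channel values (no sRGB linearization); L*a*b* and
#' L*u*v* use the sRGB matrix with D65 white, hue channels are scaled to
#' \[0,1), and YCbCr/YUV both use BT.601 luma with their respective standard
#' chroma scalings.
#'
#' @param image A height x width x 3 array in \[0,1\] (see [read_image()]).
#' @param space One of `"LAB"`, `"LUV"`, `"HSV"`, `"HSI"`, `"YCbCr"`,
#'   `"YUV"` (case-insensitive).
#' @return A height x width x 3 numeric array of the converted channels.
#' @export
#' @examples
#' img <- array(c(0, 1, 0), dim = c(1, 1, 3))  # pure green
#' convert_colorspace(img, "HSV")[1, 1, ]      # hue 1/3
convert_colorspace <- function(image, space) {
  validate_image(image)
  sp <- toupper(space)
  if (length(sp) != 1L || !sp %in% COLOR_SPACES) {
    stop("unknown colour space '", space, "': valid names are ",
         "LAB, LUV, HSV, HSI, YCbCr, YUV", call. = FALSE)
  }
  fun <- switch(sp,
    LAB = rgb_to_lab, LUV = rgb_to_luv, HSV = rgb_to_hsv,
    HSI = rgb_to_hsi, YCBCR = rgb_to_ycbcr, YUV = rgb_to_yuv)
  out <- fun(flatten_rgb(image))
  h <- dim(image)[1L]; w <- dim(image)[2L]
  array(c(unflatten(out[, 1L], h, w),
          unflatten(out[, 2L], h, w),
          unflatten(out[, 3L], h, w)),
        dim = dim(image))
}
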