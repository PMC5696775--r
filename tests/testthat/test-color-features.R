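test_that("feature matrix has 21 named columns, one row per pixel", {
  img <- rand_img(4, 6, seed = 2)
  f <- extract_features(img)
  expect_identical(dim(f), c(24L, 21L))
  expect_identical(colnames(f), mfl_feature_names())
  expect_length(mfl_feature_names(), 21L)
})

test_that("rows follow row-major pixel order and f1..f3 are raw RGB", {
  img <- rand_img(3, 5, seed = 3)
  f <- extract_features(img)
  # pixel at 0-based (1, 2) is row 1*5 + 2 + 1 = 8
  expect_equal(unname(f[8, 1:3]), img[2, 3, ])
})

test_that("the shared L* column is duplicated exactly (f4 == f7)", {
  f <- extract_features(rand_img(5, 5, seed = 4))
  expect_equal(f[, "Lab_L"], f[, "Luv_L"])
})

test_that("achromatic pixels have zero chroma and zero saturation", {
  for (v in c(0.25, 0.5, 0.9)) {
    f <- extract_features(flat_img(1, 1, c(v, v, v)))
    expect_equal(unname(f[1, c("Lab_a", "Lab_b")]), c(0, 0),
                 tolerance = 1e-9)
    expect_equal(unname(f[1, c("Luv_u", "Luv_v")]), c(0, 0),
                 tolerance = 1e-9)
    expect_equal(unname(f[1, c("HSV_S", "HSI_S")]), c(0, 0),
                 tolerance = 1e-12)
    expect_equal(unname(f[1, "HSV_V"]), v)
  }
})

test_that("primary hues follow the standard hexcone", {
  red <- extract_features(flat_img(1, 1, c(1, 0, 0)))
  expect_equal(unname(red[1, c("HSV_H", "HSV_S", "HSV_V")]), c(0, 1, 1))
  green <- extract_features(flat_img(1, 1, c(0, 1, 0)))
  expect_equal(unname(green[1, "HSV_H"]), 1 / 3)
  expect_equal(unname(green[1, 1:3]), c(0, 1, 0))
  blue <- extract_features(flat_img(1, 1, c(0, 0, 1)))
  expect_equal(unname(blue[1, "HSV_H"]), 2 / 3)
})

test_that("white maps to L* = 100 with zero chroma under D65", {
  f <- extract_features(flat_img(1, 1, c(1, 1, 1)))
  expect_equal(unname(f[1, "Lab_L"]), 100, tolerance = 1e-3)
  expect_equal(unname(f[1, c("Lab_a", "Lab_b", "Luv_u", "Luv_v")]),
               c(0, 0, 0, 0), tolerance = 1e-2)
})

test_that("vectorized CIE conversions match a scalar reimplementation", {
  set.seed(11)
  px <- matrix(runif(15), 5, 3)
  f <- extract_features(array(px, dim = c(1, 5, 3)))
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  wh <- rowSums(M)  # package convention: white = matrix row sums (D65)
  lf <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else
    t / (3 * (6 / 29)^2) + 4 / 29
  for (i in 1:5) {
    xyz <- as.vector(M %*% px[i, ])
    L <- 116 * lf(xyz[2] / wh[2]) - 16
    a <- 500 * (lf(xyz[1] / wh[1]) - lf(xyz[2] / wh[2]))
    b <- 200 * (lf(xyz[2] / wh[2]) - lf(xyz[3] / wh[3]))
    expect_equal(unname(f[i, c("Lab_L", "Lab_a", "Lab_b")]),
                 c(L, a, b), tolerance = 1e-9)
    den <- xyz[1] + 15 * xyz[2] + 3 * xyz[3]
    dn <- wh[1] + 15 * wh[2] + 3 * wh[3]
    u <- 13 * L * (4 * xyz[1] / den - 4 * wh[1] / dn)
    v <- 13 * L * (9 * xyz[2] / den - 9 * wh[2] / dn)
    expect_equal(unname(f[i, c("Luv_u", "Luv_v")]), c(u, v),
                 tolerance = 1e-9)
  }
})

test_that("RGB -> HSV -> RGB round trip is exact to 1e-9", {
  set.seed(12)
  rgb <- matrix(runif(300), 100, 3)
  hsv <- canopyseg:::rgb_to_hsv(rgb)
  back <- canopyseg:::hsv_to_rgb(hsv)
  expect_equal(unname(back), unname(rgb), tolerance = 1e-9)
})

test_that("HSV and HSI hues describe the same angle", {
  # exact agreement at the primaries ...
  for (rgb in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    f <- extract_features(flat_img(1, 1, rgb))
    expect_equal(unname(f[1, "HSV_H"]), unname(f[1, "HSI_H"]),
                 tolerance = 1e-9)
  }
  # ... and closely elsewhere for saturated colours
  set.seed(13)
  for (k in 1:25) {
    rgb <- runif(3)
    rgb[which.min(rgb)] <- 0  # fully saturated
    f <- extract_features(flat_img(1, 1, rgb))
    d <- abs(f[1, "HSV_H"] - f[1, "HSI_H"])
    expect_lt(min(d, 1 - d), 0.02)
  }
})

test_that("the two luma columns agree; the chroma scalings differ", {
  set.seed(14)
  px <- matrix(runif(30), 10, 3)
  f <- extract_features(array(px, dim = c(2, 5, 3)))
  expect_equal(f[, "YCbCr_Y"], f[, "YUV_Y"])
  y <- 0.299 * f[, "R"] + 0.587 * f[, "G"] + 0.114 * f[, "B"]
  expect_equal(unname(f[, "YUV_U"]), unname(0.492 * (f[, "B"] - y)),
               tolerance = 1e-12)
  expect_equal(unname((f[, "YCbCr_Cb"] - 0.5) * 1.772),
               unname(f[, "B"] - y), tolerance = 1e-12)
})

test_that("all 21 features are finite for extreme inputs", {
  for (rgb in list(c(0, 0, 0), c(1, 1, 1), c(1, 0, 0), c(0, 1, 0),
                   c(0, 0, 1), c(1, 1, 0), c(0, 1, 1))) {
    expect_true(all(is.finite(extract_features(flat_img(1, 1, rgb)))))
  }
})

test_that("feature extraction is per-pixel: permuting pixels permutes rows", {
  img <- rand_img(1, 8, seed = 15)
  rev_img <- img[, 8:1, , drop = FALSE]
  expect_equal(extract_features(rev_img),
               extract_features(img)[8:1, ])
})

test_that("convert_colorspace validates its space argument", {
  img <- rand_img(2, 2, seed = 16)
  expect_error(convert_colorspace(img, "XYZ"), "LAB, LUV, HSV")
  out <- convert_colorspace(img, "ycbcr")  # case-insensitive
  expect_identical(dim(out), dim(img))
})
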