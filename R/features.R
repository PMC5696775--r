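#' Names of the 21 per-pixel colour features
#'
#' The fixed column order of the multi-feature representation: the raw R, G,
#' B channels followed by the six colour-space conversions
#' (L*a*b*, L*u*v*, HSV, HSI, YCbCr, YUV). The L* column appears twice
#' (once with each CIE space); the two luma columns share BT.601
#' coefficients but the chroma pairs differ, so all 21 columns are kept.
#'
#' @return A character vector of length 21.
#' @export
mfl_feature_names <- function() {
  c("R", "G", "B",
    "Lab_L", "Lab_a", "Lab_b",
    "Luv_L", "Luv_u", "Luv_v",
    "HSV_H", "HSV_S", "HSV_V",
    "HSI_H", "HSI_S", "HSI_I",
    "YCbCr_Y", "YCbCr_Cb", "YCbCr_Cr",
    "YUV_Y", "YUV_U", "YUV_V")
}

#' Extract the 21-column multi-colour-space feature matrix
#'
#' Describes every pixel of an RGB image by a 21-element feature vector:
#' its R, G, B values plus its coordinates in L*a*b*, L*u*v*, HSV, HSI,
#' YCbCr and YUV. Rows follow row-major pixel order (row `i` of the matrix,
#' 1-based, is image pixel at 0-based coordinates
#' `((i-1) %/% width, (i-1) %% width)`).
#'
#' @param image A height x width x 3 array in \[0,1\].
#' @return A numeric matrix with `height * width` rows and 21 named columns
#'   (see [mfl_feature_names()]).
#' @export
#' @examples
#' img <- array(runif(2 * 3 * 3), dim = c(2, 3, 3))
#' f <- extract_features(img)
#' dim(f)          # 6 x 21
#' colnames(f)[1:3]
extract_features <- function(image) {
  validate_image(image)
  rgb <- flatten_rgb(image)
  out <- cbind(rgb,
               rgb_to_lab(rgb),
               rgb_to_luv(rgb),
               rgb_to_hsv(rgb),
               rgb_to_hsi(rgb),
               rgb_to_ycbcr(rgb),
               rgb_to_yuv(rgb))
  colnames(out) <- mfl_feature_names()
  out
}
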