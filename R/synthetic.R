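# Synthetic canopy-scene generator: brown/grey textured soil, elongated
# green foliage blobs with exact ground truth, cast shadows (brightness
# attenuation), specular highlights (near-saturated white spots on foliage),
# per-channel colour-temperature gains and sensor noise. Every segmenter and
# metric in the package is testable against these scenes without any field
# imagery.

#' Parameters of a synthetic canopy scene
#'
#' The defaults describe the nominal benchmark condition used throughout
#' the package: a 128 x 128 scene with 30% green cover, 30% of the area in
#' diffuse cast shadow at 0.55 brightness, two specular highlights per
#' kilopixel, neutral colour balance and mild sensor noise.
#'
#' @param width,height Scene dimensions in pixels.
#' @param target_cover Fraction of pixels that should be foliage; blob
#'   placement stops once the realized cover is within 0.05 of this target
#'   (0 and 1 are honoured exactly).
#' @param foliage_hue_range Interval of HSV hues (on \[0,1)) foliage greens
#'   are drawn from.
#' @param soil_palette A matrix with 3 columns of \[0,1\] RGB rows; soil
#'   colours are spatially correlated mixtures of these.
#' @param shadow_fraction Fraction of the scene area under cast shadow.
#' @param shadow_attenuation Brightness multiplier inside shadows, in
#'   (0, 1\].
#' @param specular_density Specular highlights per kilopixel; highlights
#'   overwrite foliage pixels with near-saturated white but remain plant in
#'   the ground truth.
#' @param colour_temperature_shift Per-channel multiplicative gain triple
#'   emulating daylight colour-temperature shifts.
#' @param noise_sd Standard deviation of per-channel Gaussian sensor noise.
#' @param seed Integer seed; the whole scene is deterministic given the
#'   parameters.
#' @return An object of class `"scene_params"`.
#' @export
scene_params <- function(width = 128L, height = 128L, target_cover = 0.3,
                         foliage_hue_range = c(0.22, 0.42),
                         soil_palette = default_soil_palette(),
                         shadow_fraction = 0.3,
                         shadow_attenuation = 0.55,
                         specular_density = 2,
                         colour_temperature_shift = c(1, 1, 1),
                         noise_sd = 0.02,
                         seed = 0L) {
  p <- list(width = as.integer(width), height = as.integer(height),
            target_cover = target_cover,
            foliage_hue_range = foliage_hue_range,
            soil_palette = soil_palette,
            shadow_fraction = shadow_fraction,
            shadow_attenuation = shadow_attenuation,
            specular_density = specular_density,
            colour_temperature_shift = colour_temperature_shift,
            noise_sd = noise_sd,
            seed = as.integer(seed))
  if (p$width < 8L || p$height < 8L) {
    stop("scene must be at least 8x8 pixels", call. = FALSE)
  }
  if (p$target_cover < 0 || p$target_cover > 1 ||
      p$shadow_fraction < 0 || p$shadow_fraction > 1) {
    stop("target_cover and shadow_fraction must lie in [0, 1]",
         call. = FALSE)
  }
  if (p$shadow_attenuation <= 0 || p$shadow_attenuation > 1) {
    stop("shadow_attenuation must lie in (0, 1]", call. = FALSE)
  }
  if (any(p$colour_temperature_shift <= 0)) {
    stop("colour-temperature gains must be positive", call. = FALSE)
  }
  if (p$noise_sd < 0 || p$specular_density < 0) {
    stop("noise_sd and specular_density must be non-negative",
         call. = FALSE)
  }
  if (length(p$foliage_hue_range) != 2L ||
      diff(p$foliage_hue_range) < 0) {
    stop("foliage_hue_range must be an increasing hue interval",
         call. = FALSE)
  }
  structure(p, class = "scene_params")
}

#' @rdname scene_params
#' @export
default_soil_palette <- function() {
  matrix(c(0.45, 0.36, 0.26,   # mid brown
           0.55, 0.47, 0.36,   # light tan
           0.33, 0.27, 0.20,   # dark brown
           0.52, 0.50, 0.46,   # grey
           0.33, 0.43, 0.26),  # greenish moss/residue
         ncol = 3L, byrow = TRUE)
}

# spatially correlated standard-normal field: coarse white noise upsampled
# bilinearly to h x w
smooth_field <- function(h, w, cell = 12L) {
  ch <- max(2L, ceiling(h / cell) + 1L)
  cw <- max(2L, ceiling(w / cell) + 1L)
  g <- matrix(stats::rnorm(ch * cw), ch, cw)
  f <- EBImage::imageData(EBImage::resize(g, w = h, h = w,
                                          filter = "bilinear"))
  (f - mean(f)) / max(stats::sd(f), 1e-12)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate a synthetic canopy scene with exact ground truth
#'
#' Renders soil, lays down elongated green foliage blobs until the realized
#' cover is within 0.05 of `target_cover`, records the exact ground-truth
#' mask, then corrupts the image with shadows, specular highlights,
#' colour-temperature gains and Gaussian noise. Corruptions never alter the
#' truth mask.
#'
#' @param params A [scene_params()] object.
#' @return An object of class `"synthetic_scene"`: a list with `image`
#'   (height x width x 3 array), `truth` (logical mask), `params` and
#'   `realized_cover`.
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  set.seed(params$seed)
  h <- params$height; w <- params$width
  img <- render_soil(h, w, params$soil_palette)
  truth <- matrix(FALSE, h, w)

  if (params$target_cover == 1) {
    truth[] <- TRUE
    img <- render_full_foliage(h, w, params$foliage_hue_range)
  } else if (params$target_cover > 0) {
    base <- min(h, w)
    max_place <- 5000L
    placed <- 0L
    while (mean(truth) < params$target_cover - 0.05) {
      placed <- placed + 1L
      if (placed > max_place) {
        stop(sprintf(
          "could not reach target cover %.2f with the blob geometry;%s",
          params$target_cover,
          sprintf(" achieved cover %.3f", mean(truth))), call. = FALSE)
      }
      blob <- foliage_blob(h, w, base, params$foliage_hue_range)
      truth[blob$cells] <- TRUE
      for (k in 1:3) {
        ch_mat <- img[, , k]
        ch_mat[blob$cells] <- blob$rgb[, k]
        img[, , k] <- ch_mat
      }
    }
  }
  realized <- mean(truth)

  # cast shadows: coherent regions, both classes attenuated
  if (params$shadow_fraction > 0 && params$shadow_attenuation < 1) {
    f <- smooth_field(h, w, cell = 16L)
    smask <- f >= stats::quantile(f, 1 - params$shadow_fraction)
    att <- ifelse(smask, params$shadow_attenuation, 1)
    for (k in 1:3) img[, , k] <- img[, , k] * att
  }

  # specular highlights: near-saturated white spots on foliage only;
  # the truth mask keeps them labelled plant
  n_spots <- round(params$specular_density * h * w / 1000)
  plant_idx <- which(truth)
  if (n_spots > 0 && length(plant_idx) > 0) {
    centres <- plant_idx[sample.int(length(plant_idx),
                                    min(n_spots, length(plant_idx)))]
    spot <- spot_cells(centres, h, w)
    spot <- spot[truth[spot]]
    for (k in 1:3) {
      ch_mat <- img[, , k]
      ch_mat[spot] <- stats::runif(length(spot), 0.95, 1)
      img[, , k] <- ch_mat
    }
  }

  gains <- params$colour_temperature_shift
  for (k in 1:3) img[, , k] <- img[, , k] * gains[k]
  if (params$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), sd = params$noise_sd)
  }
  img <- clip01(img)

  structure(list(image = img, truth = truth, params = params,
                 realized_cover = realized),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "Synthetic canopy scene: %dx%d px, cover %.3f (target %.2f), seed %d\n",
    x$params$height, x$params$width, x$realized_cover,
    x$params$target_cover, x$params$seed))
  invisible(x)
}

# every scene mixes all palette components, so each soil type (incl. the
# greenish residue patches that fool colour indices) is present in every
# plot, with soft spatially correlated transitions
render_soil <- function(h, w, palette) {
  np <- nrow(palette)
  wts <- array(0, dim = c(h, w, np))
  for (p in seq_len(np)) wts[, , p] <- exp(2 * smooth_field(h, w, 10L))
  tot <- apply(wts, c(1L, 2L), sum)
  bright <- 1 + 0.12 * tanh(smooth_field(h, w, cell = 6L))
  img <- array(0, dim = c(h, w, 3L))
  for (k in 1:3) {
    acc <- matrix(0, h, w)
    for (p in seq_len(np)) acc <- acc + wts[, , p] * palette[p, k]
    img[, , k] <- clip01(acc / tot * bright)
  }
  img
}

render_full_foliage <- function(h, w, hue_range) {
  hue <- clip01(mean(hue_range) +
                  diff(hue_range) / 2 * tanh(smooth_field(h, w, 8L)) / 2)
  val <- clip01(0.55 + 0.25 * tanh(smooth_field(h, w, 8L)))
  rgb <- hsv_to_rgb(cbind(as.vector(hue), 0.75, as.vector(val)))
  array(c(matrix(rgb[, 1L], h, w), matrix(rgb[, 2L], h, w),
          matrix(rgb[, 3L], h, w)), dim = c(h, w, 3L))
}

# one elongated leaf-like elliptical blob; returns linear cell indices and
# per-cell RGB colours
foliage_blob <- function(h, w, base, hue_range) {
  repeat {
    cy <- stats::runif(1L, 1, h)
    cx <- stats::runif(1L, 1, w)
    a <- stats::runif(1L, 0.14, 0.24) * base        # half length
    b <- max(4, stats::runif(1L, 0.055, 0.085) * base)   # half width
    th <- stats::runif(1L, 0, pi)
    r0 <- max(1L, floor(cy - a)); r1 <- min(h, ceiling(cy + a))
    c0 <- max(1L, floor(cx - a)); c1 <- min(w, ceiling(cx + a))
    rows <- r0:r1; cols <- c0:c1
    dy <- matrix(rows - cy, length(rows), length(cols))
    dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
    xr <- dx * cos(th) + dy * sin(th)
    yr <- -dx * sin(th) + dy * cos(th)
    inside <- (xr / a)^2 + (yr / b)^2 <= 1
    if (!any(inside)) next  # blob centred too far outside; redraw
    sub <- which(inside, arr.ind = TRUE)
    cells <- (c0 - 1L + sub[, 2L] - 1L) * h + (r0 - 1L + sub[, 1L])
    hue <- stats::runif(1L, hue_range[1L], hue_range[2L])
    sat <- stats::runif(1L, 0.50, 0.70)
    val <- stats::runif(1L, 0.38, 0.60)
    val_px <- clip01(val + stats::rnorm(length(cells), sd = 0.05))
    return(list(cells = cells,
                rgb = hsv_to_rgb(cbind(hue, sat, val_px))))
  }
}

# plus-shaped 5-cell spots around linear-index centres, kept in bounds
spot_cells <- function(centres, h, w) {
  r <- (centres - 1L) %% h + 1L
  c <- (centres - 1L) %/% h + 1L
  dr <- c(0L, 1L, -1L, 0L, 0L)
  dc <- c(0L, 0L, 0L, 1L, -1L)
  rr <- rep(r, each = 5L) + dr
  cc <- rep(c, each = 5L) + dc
  ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
  unique((cc[ok] - 1L) * h + rr[ok])
}

#' Generate a labelled patch dataset from synthetic scenes
#'
#' Renders scenes from `params` (with scene seeds derived from
#' `params$seed`) and harvests square crops that are entirely foliage
#' (positive patches, including shadowed and highlighted variants) or
#' entirely soil (negative patches). Purity is with respect to the exact
#' ground truth, so every positive patch's truth sub-mask is all plant.
#'
#' To emulate a patch library collected across acquisition days and
#' weathers, each internal scene is rendered under its own illumination:
#' a colour-temperature gain drawn along the warm-cool daylight axis
#' (spanning the [day_course_gains()] envelope) and a +/-10% brightness
#' jitter, both derived from `params$seed`.
#'
#' @param params A [scene_params()] object.
#' @param n_positive,n_negative Number of plant / background patches.
#' @param crop_sizes Integer vector of candidate crop side lengths.
#' @return A [patch_dataset()].
#' @export
generate_patch_dataset <- function(params, n_positive = 200L,
                                   n_negative = 120L,
                                   crop_sizes = 10:16) {
  stopifnot(inherits(params, "scene_params"))
  if (n_positive < 1L || n_negative < 1L) {
    stop("patch counts must be >= 1", call. = FALSE)
  }
  max_scenes <- 60L
  set.seed(params$seed)
  scene_seeds <- sample.int(2^20, max_scenes)
  warmth <- stats::runif(max_scenes, -1, 1)   # cool (blue) .. warm (red)
  brightness <- stats::runif(max_scenes, 0.9, 1.1)
  images <- list(); labels <- character(0L); ids <- character(0L)
  got_fg <- 0L; got_bg <- 0L
  for (si in seq_len(max_scenes)) {
    if (got_fg >= n_positive && got_bg >= n_negative) break
    p2 <- params
    p2$seed <- scene_seeds[si]
    t <- warmth[si]
    p2$colour_temperature_shift <- params$colour_temperature_shift *
      brightness[si] * c(1 + 0.18 * t, 1 - 0.02 * abs(t), 1 - 0.20 * t)
    scene <- generate_scene(p2)
    h <- nrow(scene$truth); w <- ncol(scene$truth)
    # cap the harvest per scene so the library spans many scenes and
    # illumination conditions rather than a handful of renders
    cap_fg <- got_fg + max(10L, ceiling(n_positive / 10))
    cap_bg <- got_bg + max(6L, ceiling(n_negative / 10))
    sat <- rbind(0, apply(matrix(as.numeric(scene$truth), h, w), 2L,
                          cumsum))
    sat <- cbind(0, t(apply(sat, 1L, cumsum)))
    for (try in seq_len(800L)) {
      if ((got_fg >= cap_fg || got_fg >= n_positive) &&
          (got_bg >= cap_bg || got_bg >= n_negative)) break
      k <- crop_sizes[sample.int(length(crop_sizes), 1L)]
      r <- sample.int(h - k + 1L, 1L)
      c <- sample.int(w - k + 1L, 1L)
      s <- sat[r + k, c + k] - sat[r, c + k] - sat[r + k, c] + sat[r, c]
      if (s == k * k && got_fg < min(cap_fg, n_positive)) {
        got_fg <- got_fg + 1L
        images[[length(images) + 1L]] <-
          scene$image[r:(r + k - 1L), c:(c + k - 1L), , drop = FALSE]
        labels <- c(labels, "plant")
        ids <- c(ids, sprintf("scene%d_fg_%d_%d", scene_seeds[si], r, c))
      } else if (s == 0 && got_bg < min(cap_bg, n_negative)) {
        got_bg <- got_bg + 1L
        images[[length(images) + 1L]] <-
          scene$image[r:(r + k - 1L), c:(c + k - 1L), , drop = FALSE]
        labels <- c(labels, "background")
        ids <- c(ids, sprintf("scene%d_bg_%d_%d", scene_seeds[si], r, c))
      }
    }
  }
  if (got_fg < n_positive || got_bg < n_negative) {
    stop(sprintf(
      "scenes too small to yield pure-class crops: found %d/%d plant and %d/%d background patches",
      got_fg, n_positive, got_bg, n_negative), call. = FALSE)
  }
  patch_dataset(images, labels, ids)
}

#' Re-render a scene under a schedule of illumination gains
#'
#' Applies each per-channel gain triple to the scene's image (then clips to
#' \[0,1\]), keeping geometry and ground truth fixed — a simulated
#' day-course of colour-temperature/brightness changes over one plot, so
#' FVC stability across illumination can be measured against a single
#' truth.
#'
#' @param scene A [generate_scene()] result.
#' @param gain_schedule A list of positive gain triples `c(r, g, b)`.
#' @return A list of height x width x 3 image arrays, one per gain triple.
#' @export
day_course <- function(scene, gain_schedule) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (length(gain_schedule) == 0L) {
    stop("gain_schedule must be non-empty", call. = FALSE)
  }
  lapply(gain_schedule, function(g) {
    if (length(g) != 3L || any(g <= 0)) {
      stop("each gain triple must be three positive numbers",
           call. = FALSE)
    }
    out <- scene$image
    for (k in 1:3) out[, , k] <- out[, , k] * g[k]
    clip01(out)
  })
}

#' Default 4-step day-course gain schedule
#'
#' Four per-channel gain triples emulating the colour-temperature drift of
#' daylight across one day: cool bluish morning, neutral midday, slightly
#' warm afternoon, strongly warm low sun.
#'
#' @return A list of four gain triples.
#' @export
day_course_gains <- function() {
  list(c(0.90, 1.00, 1.14),
       c(1.00, 1.00, 1.00),
       c(1.08, 1.00, 0.92),
       c(1.22, 0.97, 0.78))
}
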