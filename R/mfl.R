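# The multi-feature learning (MFL) segmenter: a two-class random forest on
# 21-colour-feature pixel vectors, trained from small labelled image patches,
# followed by median-filter denoising of the predicted mask.

#' Build a labelled patch dataset
#'
#' Bundles plant (positive) and background (negative) training crops into
#' the dataset structure consumed by [mfl()].
#'
#' @param images A list of height x width x 3 arrays in \[0,1\].
#' @param labels A vector (one per image) of class labels: `1`/`"plant"`/
#'   `TRUE` for vegetation, `0`/`"background"`/`FALSE` for background.
#' @param source_ids Optional character vector of provenance tags.
#' @return An object of class `"patch_dataset"` with elements `patches`
#'   (list of `image`/`label`/`source_id`), `n_positive` and `n_negative`.
#' @export
patch_dataset <- function(images, labels, source_ids = NULL) {
  if (length(images) == 0L) {
    stop("patch dataset is empty: at least one labelled patch is required",
         call. = FALSE)
  }
  if (length(labels) != length(images)) {
    stop("'labels' must have one entry per patch image", call. = FALSE)
  }
  lab <- vapply(labels, normalize_label, character(1L))
  if (is.null(source_ids)) {
    source_ids <- sprintf("patch_%d", seq_along(images))
  }
  patches <- Map(function(im, l, s) {
    validate_image(im)
    list(image = im, label = l, source_id = s)
  }, images, lab, source_ids)
  structure(
    list(patches = patches,
         n_positive = sum(lab == "plant"),
         n_negative = sum(lab == "background")),
    class = "patch_dataset")
}

normalize_label <- function(x) {
  if (isTRUE(x) || identical(x, 1) || identical(x, 1L) ||
      identical(x, "plant") || identical(x, "+1") || identical(x, "1") ||
      identical(x, "fg")) {
    "plant"
  } else if (isFALSE(x) || identical(x, 0) || identical(x, 0L) ||
             identical(x, "background") || identical(x, "0") ||
             identical(x, "bg")) {
    "background"
  } else {
    stop("unrecognized patch label '", x,
         "': use plant/1/TRUE or background/0/FALSE", call. = FALSE)
  }
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat("Labelled patch dataset:", length(x$patches), "patches",
      sprintf("(%d plant, %d background)\n", x$n_positive, x$n_negative))
  invisible(x)
}

#' Read a patch dataset from directories or a manifest
#'
#' Patches are individual image files. Either give a two-column CSV manifest
#' (`path,label`) or one directory per class.
#'
#' @param fg_dir,bg_dir Directories of plant / background patch images.
#' @param manifest Path to a CSV with columns `path` and `label`
#'   (overrides the directories when given).
#' @return A [patch_dataset()].
#' @export
read_patch_dataset <- function(fg_dir = NULL, bg_dir = NULL,
                               manifest = NULL) {
  if (!is.null(manifest)) {
    tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    if (!all(c("path", "label") %in% names(tab))) {
      stop("manifest must have columns 'path' and 'label'", call. = FALSE)
    }
    paths <- ifelse(file.exists(tab$path), tab$path,
                    file.path(dirname(manifest), tab$path))
    labels <- as.character(tab$label)
  } else {
    if (is.null(fg_dir) || is.null(bg_dir)) {
      stop("give either 'manifest' or both 'fg_dir' and 'bg_dir'",
           call. = FALSE)
    }
    fg <- sort(list.files(fg_dir, full.names = TRUE,
                          pattern = "\\.(png|jpe?g|tiff?)$"))
    bg <- sort(list.files(bg_dir, full.names = TRUE,
                          pattern = "\\.(png|jpe?g|tiff?)$"))
    paths <- c(fg, bg)
    labels <- c(rep("plant", length(fg)), rep("background", length(bg)))
  }
  patch_dataset(lapply(paths, read_image), labels, source_ids = paths)
}

#' Build the pixel-level training matrix from a patch dataset
#'
#' Every patch is resized to `patch_size` x `patch_size` pixels (bilinear),
#' its 21-column feature matrix is extracted, and the rows of all patches
#' are stacked with the patch's class label replicated across its pixels.
#'
#' @param dataset A [patch_dataset()].
#' @param patch_size Side length the patches are resized to (default 20).
#' @return A list with `features` (`n_patches * patch_size^2` x 21 matrix)
#'   and `labels` (factor with levels `background`, `plant`).
#' @export
build_training_matrix <- function(dataset, patch_size = 20L) {
  stopifnot(inherits(dataset, "patch_dataset"))
  if (patch_size < 1L) stop("patch_size must be >= 1", call. = FALSE)
  feats <- vector("list", length(dataset$patches))
  labels <- character(0L)
  for (i in seq_along(dataset$patches)) {
    p <- dataset$patches[[i]]
    d <- dim(p$image)
    if (d[1L] < 2L || d[2L] < 2L) {
      warning("patch ", p$source_id, " is smaller than 2x2; ",
              "resizing anyway", call. = FALSE)
    }
    feats[[i]] <- extract_features(resize_patch(p$image, patch_size))
    labels <- c(labels, rep(p$label, patch_size^2))
  }
  list(features = do.call(rbind, feats),
       labels = factor(labels, levels = c("background", "plant")))
}

# bilinear resize to size x size, clamped back to [0,1]
resize_patch <- function(image, size) {
  if (dim(image)[1L] == size && dim(image)[2L] == size) return(image)
  out <- EBImage::imageData(
    EBImage::resize(image, w = size, h = size, filter = "bilinear"))
  array(pmin(pmax(out, 0), 1), dim = c(size, size, 3L))
}

#' Fit the multi-feature learning (MFL) pixel classifier
#'
#' Trains a two-class probability random forest on the 21-colour-feature
#' vectors of every pixel of the (resized) training patches. This is the
#' model-fitting entry point of the package; segment images with
#' [predict.mfl()] or [segment_mfl()].
#'
#' @param dataset A [patch_dataset()] containing both classes.
#' @param trees Number of trees in the forest (default 100).
#' @param patch_size Side length patches are resized to (default 20).
#' @param seed Integer seed; with `num_threads = 1` the fit is
#'   bit-reproducible.
#' @param mtry Features tried per split (default `floor(sqrt(21)) = 4`).
#' @param num_threads Threads used by the forest (default 1 for
#'   determinism).
#' @return An object of class `"mfl"`: the fitted forest plus
#'   `feature_order`, hyperparameters and a `training_summary` holding the
#'   patch counts (`n_positive`, `n_negative`) and pixel-row counts.
#' @seealso [predict.mfl()], [segment_mfl()], [denoise_mask()]
#' @export
mfl <- function(dataset, trees = 100L, patch_size = 20L, seed = 0L,
                mtry = 4L, num_threads = 1L) {
  stopifnot(inherits(dataset, "patch_dataset"))
  if (dataset$n_positive == 0L) {
    stop("training data has no 'plant' patches; both classes are required",
         call. = FALSE)
  }
  if (dataset$n_negative == 0L) {
    stop("training data has no 'background' patches; ",
         "both classes are required", call. = FALSE)
  }
  tm <- build_training_matrix(dataset, patch_size)
  df <- data.frame(tm$features, .label = tm$labels, check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = ".label",
    data = df,
    num.trees = trees,
    mtry = mtry,
    probability = TRUE,
    seed = seed,
    num.threads = num_threads,
    verbose = FALSE)
  structure(
    list(forest = fit,
         feature_order = mfl_feature_names(),
         trees = trees,
         patch_size = patch_size,
         seed = seed,
         mtry = mtry,
         training_summary = list(
           n_positive = dataset$n_positive,
           n_negative = dataset$n_negative,
           n_rows_positive = as.integer(dataset$n_positive * patch_size^2),
           n_rows_negative = as.integer(dataset$n_negative * patch_size^2)),
         format_version = 1L),
    class = "mfl")
}

#' @export
print.mfl <- function(x, ...) {
  s <- x$training_summary
  cat("Multi-feature learning (MFL) vegetation segmenter\n")
  cat(sprintf("  forest: %d trees, mtry %d, seed %d\n",
              x$trees, x$mtry, x$seed))
  cat(sprintf("  trained on %d plant + %d background patches (%dx%d)\n",
              s$n_positive, s$n_negative, x$patch_size, x$patch_size))
  cat(sprintf("  pixel rows: %d plant, %d background, 21 features\n",
              s$n_rows_positive, s$n_rows_negative))
  invisible(x)
}

#' @export
summary.mfl <- function(object, ...) {
  print(object)
  cat(sprintf("  out-of-bag prediction error: %.4f\n",
              object$forest$prediction.error))
  invisible(object)
}

#' Predict a vegetation mask (or probability map) for an image
#'
#' Extracts the 21 colour features of every pixel and aggregates the
#' forest's per-tree class distributions into a plant probability. With
#' `type = "mask"` a pixel is plant iff its probability strictly exceeds
#' `prob_threshold` (so a threshold of 1 yields all background). No
#' denoising is applied here; see [segment_mfl()] for the full pipeline.
#'
#' @param object A fitted [mfl()] model.
#' @param image A height x width x 3 array in \[0,1\].
#' @param type `"mask"` (logical matrix) or `"prob"` (probability matrix).
#' @param prob_threshold Decision threshold on the plant probability
#'   (default 0.5).
#' @param ... Unused.
#' @return A logical or numeric height x width matrix.
#' @export
predict.mfl <- function(object, image, type = c("mask", "prob"),
                        prob_threshold = 0.5, ...) {
  type <- match.arg(type)
  validate_image(image)
  feats <- extract_features(image)
  if (!identical(colnames(feats), object$feature_order)) {
    stop("feature order of the model does not match the extractor: ",
         "the model was built with an incompatible feature set",
         call. = FALSE)
  }
  pred <- stats::predict(object$forest,
                         data = data.frame(feats, check.names = FALSE),
                         num.threads = 1L, verbose = FALSE)
  prob <- pred$predictions[, "plant"]
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (type == "prob") unflatten(prob, h, w)
  else unflatten(prob > prob_threshold, h, w)
}

#' Median-filter denoising of a binary mask
#'
#' Slides an odd `window` x `window` neighbourhood over the mask and
#' replaces each pixel by the median of the window — for a two-valued mask,
#' the majority class. Borders use reflect padding. Removes isolated
#' misclassified pixels while preserving solid regions.
#'
#' @param mask A logical plant/background matrix.
#' @param window Odd window side length in pixels (default 7).
#' @return A logical matrix of the same dimensions.
#' @export
denoise_mask <- function(mask, window = 7L) {
  validate_mask(mask)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be an odd positive integer, got ", window,
         call. = FALSE)
  }
  if (window == 1L) return(mask)
  r <- (window - 1L) %/% 2L
  h <- nrow(mask); w <- ncol(mask)
  ri <- reflect_index(h, r)
  ci <- reflect_index(w, r)
  padded <- matrix(as.numeric(mask[ri, ci]), length(ri), length(ci))
  # summed-area table for O(1) window sums
  sat <- rbind(0, apply(padded, 2L, cumsum))
  sat <- cbind(0, t(apply(sat, 1L, cumsum)))
  i <- seq_len(h); j <- seq_len(w)
  counts <- sat[i + window, j + window, drop = FALSE] -
    sat[i, j + window, drop = FALSE] -
    sat[i + window, j, drop = FALSE] +
    sat[i, j, drop = FALSE]
  counts > window^2 / 2
}

# edge-inclusive mirror indices: for n=5, r=2 -> 2 1 | 1..5 | 5 4
reflect_index <- function(n, r) {
  if (r >= n) stop("mask too small for the requested window", call. = FALSE)
  c(rev(seq_len(r)), seq_len(n), n - seq_len(r) + 1L)
}

#' Segment an image with the full MFL pipeline
#'
#' Feature extraction, forest prediction and median-filter denoising in one
#' call: `denoise_mask(predict(model, image), window)`.
#'
#' @inheritParams predict.mfl
#' @param model A fitted [mfl()] model.
#' @param window Median-filter window (default 7).
#' @return A logical plant/background matrix.
#' @export
segment_mfl <- function(model, image, prob_threshold = 0.5, window = 7L) {
  denoise_mask(predict(model, image, type = "mask",
                       prob_threshold = prob_threshold),
               window = window)
}

#' Save / load a fitted MFL model
#'
#' The serialized model embeds a format version and the 21-entry feature
#' order; loading a model whose feature order does not match the current
#' extractor is an error rather than a silent reorder.
#'
#' @param model A fitted [mfl()] model.
#' @param path File path (conventionally `.rds`).
#' @return `write_mfl` returns `path` invisibly; `read_mfl` returns the
#'   model.
#' @export
write_mfl <- function(model, path) {
  stopifnot(inherits(model, "mfl"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_mfl
#' @export
read_mfl <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mfl") || is.null(model$format_version)) {
    stop("'", path, "' is not a serialized MFL model", call. = FALSE)
  }
  if (!identical(model$feature_order, mfl_feature_names())) {
    stop("model in '", path, "' was built with a different feature order; ",
         "refusing to load it", call. = FALSE)
  }
  model
}
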