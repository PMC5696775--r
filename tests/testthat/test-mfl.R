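# small separable fixture: saturated green foliage vs brown soil patches
separable_dataset <- function(n_fg = 6, n_bg = 4, size = 8) {
  set.seed(99)
  greens <- replicate(n_fg, {
    img <- flat_img(size, size, c(0.15, 0.6, 0.2))
    img + array(runif(size^2 * 3, -0.05, 0.05), dim = dim(img))
  }, simplify = FALSE)
  browns <- replicate(n_bg, {
    img <- flat_img(size, size, c(0.45, 0.36, 0.26))
    img + array(runif(size^2 * 3, -0.05, 0.05), dim = dim(img))
  }, simplify = FALSE)
  imgs <- lapply(c(greens, browns), function(x) pmin(pmax(x, 0), 1))
  patch_dataset(imgs, c(rep(1, n_fg), rep(0, n_bg)))
}

test_that("patch datasets book-keep their class counts", {
  ds <- separable_dataset(5, 3)
  expect_identical(ds$n_positive, 5L)
  expect_identical(ds$n_negative, 3L)
  expect_length(ds$patches, 8L)
  expect_error(patch_dataset(list(), numeric(0)), "empty")
  expect_error(patch_dataset(list(flat_img(2, 2, c(0, 1, 0))), "maybe"),
               "unrecognized")
})

test_that("training matrix stacks patch_size^2 rows per patch", {
  ds <- separable_dataset(5, 3)
  tm <- build_training_matrix(ds, patch_size = 20)
  expect_identical(dim(tm$features), c(8L * 400L, 21L))
  expect_identical(sum(tm$labels == "plant"), 2000L)
  expect_identical(levels(tm$labels), c("background", "plant"))
})

test_that("resizing a patch already at target size is the identity", {
  img <- rand_img(20, 20, seed = 41)
  ds <- patch_dataset(list(img), 1)
  tm <- build_training_matrix(ds, patch_size = 20)
  expect_equal(unname(tm$features), unname(extract_features(img)))
})

test_that("patch_size 1 reduces a uniform patch to its colour features", {
  img <- flat_img(6, 6, c(0.2, 0.7, 0.3))
  tm <- build_training_matrix(patch_dataset(list(img), 1), patch_size = 1)
  expect_identical(nrow(tm$features), 1L)
  expect_equal(unname(tm$features),
               unname(extract_features(flat_img(1, 1, c(0.2, 0.7, 0.3)))),
               tolerance = 1e-6)
})

test_that("training requires both classes and names the missing one", {
  only_fg <- patch_dataset(list(flat_img(4, 4, c(0, 1, 0))), 1)
  expect_error(mfl(only_fg), "background")
  only_bg <- patch_dataset(list(flat_img(4, 4, c(0.4, 0.3, 0.2))), 0)
  expect_error(mfl(only_bg), "plant")
})

test_that("a separable dataset is fit exactly and deterministically", {
  ds <- separable_dataset()
  model <- mfl(ds, trees = 30, seed = 5)
  expect_s3_class(model, "mfl")
  expect_identical(model$feature_order, mfl_feature_names())
  expect_identical(model$training_summary$n_rows_positive, 6L * 400L)

  probe_fg <- flat_img(5, 5, c(0.15, 0.6, 0.2))
  probe_bg <- flat_img(5, 5, c(0.45, 0.36, 0.26))
  expect_true(all(predict(model, probe_fg)))
  expect_false(any(predict(model, probe_bg)))

  model2 <- mfl(ds, trees = 30, seed = 5)
  probe <- rand_img(8, 8, seed = 42)
  expect_identical(predict(model, probe), predict(model2, probe))
  expect_identical(predict(model, probe, type = "prob"),
                   predict(model2, probe, type = "prob"))
})

test_that("probability threshold 1 yields all background", {
  model <- mfl(separable_dataset(), trees = 20, seed = 1)
  probe <- flat_img(4, 4, c(0.15, 0.6, 0.2))
  expect_false(any(predict(model, probe, prob_threshold = 1)))
})

test_that("a model with a foreign feature order refuses to predict", {
  model <- mfl(separable_dataset(), trees = 10, seed = 1)
  model$feature_order <- rev(model$feature_order)
  expect_error(predict(model, rand_img(3, 3, seed = 1)), "feature order")
})

test_that("model serialization round-trips and checks its feature order", {
  model <- mfl(separable_dataset(), trees = 10, seed = 2)
  p <- withr::local_tempfile(fileext = ".rds")
  write_mfl(model, p)
  got <- read_mfl(p)
  probe <- rand_img(5, 5, seed = 43)
  expect_identical(predict(got, probe), predict(model, probe))

  bad <- model
  bad$feature_order[1] <- "bogus"
  saveRDS(bad, p)
  expect_error(read_mfl(p), "feature order")
  saveRDS(list(a = 1), p)
  expect_error(read_mfl(p), "not a serialized")
})

test_that("median denoising keeps constants and removes isolated pixels", {
  const <- matrix(TRUE, 9, 9)
  expect_identical(denoise_mask(const, 7), const)
  expect_identical(denoise_mask(!const, 7), !const)

  lone <- matrix(FALSE, 9, 9); lone[5, 5] <- TRUE
  expect_false(any(denoise_mask(lone, 7)))
})

test_that("median denoising preserves solid block interiors", {
  m <- matrix(FALSE, 30, 30); m[6:25, 6:25] <- TRUE
  den <- denoise_mask(m, 7)
  expect_true(all(den[9:22, 9:22]))
  expect_false(any(den[1:3, ]))
})

test_that("denoise window must be odd and output stays binary", {
  m <- rand_mask(12, 12)
  expect_error(denoise_mask(m, 4), "odd")
  expect_error(denoise_mask(m, 0), "odd")
  den <- denoise_mask(m, 3)
  expect_type(den, "logical")
  expect_identical(dim(den), dim(m))
  expect_identical(denoise_mask(m, 1), m)
})

test_that("repeated denoising changes no more pixels than the first pass", {
  set.seed(44)
  for (k in 1:5) {
    m <- rand_mask(20, 20, p = runif(1, 0.2, 0.8))
    d1 <- denoise_mask(m, 5)
    d2 <- denoise_mask(d1, 5)
    expect_lte(sum(d2 != d1), sum(d1 != m))
  }
})

test_that("segment_mfl is predict + denoise and preserves dimensions", {
  model <- mfl(separable_dataset(), trees = 20, seed = 3)
  img <- rand_img(15, 13, seed = 45)
  out <- segment_mfl(model, img)
  expect_identical(dim(out), c(15L, 13L))
  expect_identical(out, denoise_mask(predict(model, img), 7))
})
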