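test_that("generation honors counts, labels, range and shape", {
  ds <- generate_dataset(synthesis_params(n_per_class = rep(10L, 4),
                                          noise_sd = 0.05, seed = 2))
  expect_equal(dim(ds$images), c(64, 64, 40))
  expect_equal(tabulate(ds$labels + 1L, 4), rep(10L, 4))
  expect_true(all(ds$images >= 0 & ds$images <= 1))
  expect_equal(ds$class_names, c("glioma", "meningioma", "notumor", "pituitary"))
  expect_error(synthesis_params(n_per_class = c(a = 1, b = 1, c = 1, d = 1)),
               "class names")
})

test_that("generation is a pure function of its parameters", {
  p <- synthesis_params(n_per_class = rep(5L, 4), noise_sd = 0.1, seed = 42)
  expect_identical(generate_dataset(p), generate_dataset(p))
  p2 <- synthesis_params(n_per_class = rep(5L, 4), noise_sd = 0.1, seed = 43)
  expect_false(identical(generate_dataset(p)$images, generate_dataset(p2)$images))
})

test_that("a nearest-template classifier is perfect on clean separable draws", {
  train <- generate_dataset(synthesis_params(n_per_class = rep(50L, 4),
                                             noise_sd = 0, class_overlap = 0,
                                             seed = 21))
  fresh <- generate_dataset(synthesis_params(n_per_class = rep(50L, 4),
                                             noise_sd = 0, class_overlap = 0,
                                             seed = 22))
  pred <- nearest_template_predict(train, fresh)
  expect_equal(mean(pred == fresh$labels), 1)
})

test_that("class-mean images are far apart relative to within-class spread", {
  ds <- generate_dataset(synthesis_params(n_per_class = rep(30L, 4),
                                          noise_sd = 0, class_overlap = 0,
                                          seed = 5))
  means <- lapply(0:3, function(cl)
    apply(ds$images[, , ds$labels == cl, drop = FALSE], c(1, 2), mean))
  pair <- utils::combn(4, 2)
  min_between <- min(apply(pair, 2, function(ij)
    sqrt(sum((means[[ij[1]]] - means[[ij[2]]]) ^ 2))))
  within <- mean(vapply(0:3, function(cl) {
    idx <- which(ds$labels == cl)
    mean(vapply(idx, function(i)
      sqrt(sum((ds$images[, , i] - means[[cl + 1]]) ^ 2)), numeric(1)))
  }, numeric(1)))
  expect_gt(min_between, 5 * within)
})

test_that("full class overlap removes the class signal from the templates", {
  hard <- generate_dataset(synthesis_params(n_per_class = rep(20L, 4),
                                            noise_sd = 0, class_overlap = 1,
                                            seed = 6))
  # with identical templates the only residual differences are jitter
  m0 <- apply(hard$images[, , hard$labels == 2, drop = FALSE], c(1, 2), mean)
  m3 <- apply(hard$images[, , hard$labels == 3, drop = FALSE], c(1, 2), mean)
  easy <- generate_dataset(synthesis_params(n_per_class = rep(20L, 4),
                                            noise_sd = 0, class_overlap = 0,
                                            seed = 6))
  e0 <- apply(easy$images[, , easy$labels == 2, drop = FALSE], c(1, 2), mean)
  e3 <- apply(easy$images[, , easy$labels == 3, drop = FALSE], c(1, 2), mean)
  expect_lt(sqrt(sum((m0 - m3) ^ 2)), 0.2 * sqrt(sum((e0 - e3) ^ 2)))
})

test_that("8-bit intensities rescale exactly", {
  expect_equal(normalize_intensity(255), 1)
  expect_equal(normalize_intensity(0), 0)
  expect_equal(normalize_intensity(51), 0.2)
  expect_error(normalize_intensity(c(-1, 3)), "0, 255")
  expect_error(normalize_intensity(256), "0, 255")
})

test_that("augmentation with all transforms disabled is the identity", {
  ds <- tiny_dataset(n_per_class = 1L)
  img <- ds$images[, , 1]
  set.seed(1)
  out <- augment_image(img, rotation_range = 0, flip_prob = 0, zoom_range = 0,
                       shift_range = 0)
  expect_identical(out, img)
})

test_that("two forced flips restore the original exactly", {
  ds <- tiny_dataset(n_per_class = 1L)
  img <- ds$images[, , 1]
  once <- augment_image(img, rotation_range = 0, flip_prob = 1, zoom_range = 0,
                        shift_range = 0)
  expect_false(identical(once, img))
  twice <- augment_image(once, rotation_range = 0, flip_prob = 1, zoom_range = 0,
                         shift_range = 0)
  expect_identical(twice, img)
})

test_that("augmentation preserves shape and range and flips at the stated rate", {
  ds <- tiny_dataset(n_per_class = 2L, noise_sd = 0.05)
  set.seed(7)
  for (i in seq_len(dim(ds$images)[3])) {
    out <- augment_image(ds$images[, , i])
    expect_equal(dim(out), c(64, 64))
    expect_true(all(out >= 0 & out <= 1))
  }
  img <- ds$images[, , 1]
  marker <- img
  marker[1, ] <- 0; marker[64, ] <- 1  # detectable orientation
  set.seed(8)
  flips <- replicate(1e4, {
    out <- augment_image(marker, rotation_range = 0, flip_prob = 0.5,
                         zoom_range = 0, shift_range = 0)
    !identical(out, marker)
  })
  expect_lt(abs(mean(flips) - 0.5), 0.02)
})

test_that("label codes follow the alphabetical class order and round-trip", {
  expect_equal(encode_labels(c("glioma", "meningioma", "notumor", "pituitary")),
               0:3)
  oh <- encode_labels("notumor", mode = "one_hot")
  expect_equal(as.vector(oh), c(0, 0, 1, 0))
  expect_equal(rowSums(encode_labels(rep(mri_class_names, 3), "one_hot")),
               rep(1, 12))
  expect_equal(decode_labels(encode_labels(c("pituitary", "glioma"))),
               c("pituitary", "glioma"))
  expect_error(encode_labels("cortex"), "unknown class")
})

test_that("a dataset written as a PNG folder reads back with the same content", {
  ds <- generate_dataset(synthesis_params(n_per_class = rep(2L, 4),
                                          noise_sd = 0.05, image_size = 32L,
                                          seed = 13))
  dir <- file.path(tempdir(), "synth_png")
  unlink(dir, recursive = TRUE)
  write_image_dir(ds, dir)
  expect_equal(sort(list.dirs(dir, full.names = FALSE, recursive = FALSE)),
               mri_class_names)
  back <- read_image_dir(dir, image_size = 32L)
  expect_equal(back$class_names, ds$class_names)
  expect_equal(tabulate(back$labels + 1L, 4), rep(2L, 4))
  # 8-bit PNG quantization bounds the round-trip error
  expect_lt(max(abs(back$images - ds$images)), 1 / 255)
})
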