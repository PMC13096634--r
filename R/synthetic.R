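#' Class names of the 4-class brain-MRI task
#'
#' Alphabetical, matching the Kaggle brain-tumor-mri-dataset folder layout;
#' integer labels 0..3 follow this order.
#' @export
mri_class_names <- c("glioma", "meningioma", "notumor", "pituitary")

#' Parameters of the synthetic image generator
#'
#' Defaults reproduce the class balance of the public brain-MRI training
#' set (1321 glioma, 1339 meningioma, 1595 no-tumor, 1457 pituitary).
#' `noise_sd` is additive Gaussian pixel noise; `class_overlap` in [0, 1]
#' interpolates every class's lesion template toward the across-class mean
#' template, hardening the task (0 = fully separable defaults, 1 =
#' identical templates).
#'
#' @param n_per_class integer vector of 4 counts, named or in class order
#'   (glioma, meningioma, notumor, pituitary).
#' @param noise_sd nonnegative Gaussian noise standard deviation.
#' @param class_overlap real in [0, 1].
#' @param image_size side length in pixels (>= 16).
#' @param seed integer seed; generation is a pure function of these
#'   parameters.
#' @return Object of class `synthesis_params`.
#' @export
synthesis_params <- function(n_per_class = c(glioma = 1321L, meningioma = 1339L,
                                             notumor = 1595L, pituitary = 1457L),
                             noise_sd = 0.05, class_overlap = 0,
                             image_size = 64L, seed = 1L) {
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, 4L)
  stopifnot(length(n_per_class) == 4L, all(n_per_class >= 1),
            noise_sd >= 0, class_overlap >= 0, class_overlap <= 1,
            image_size >= 16)
  if (!is.null(names(n_per_class))) {
    if (!setequal(names(n_per_class), mri_class_names))
      stop("n_per_class names must be the four class names")
    n_per_class <- n_per_class[mri_class_names]
  } else names(n_per_class) <- mri_class_names
  structure(list(n_per_class = as.integer(n_per_class),
                 noise_sd = noise_sd, class_overlap = class_overlap,
                 image_size = as.integer(image_size), seed = as.integer(seed)),
            class = "synthesis_params")
}

# normalized pixel-center coordinate grids in [0, 1]
.coord_grid <- function(s) {
  v <- (seq_len(s) - 0.5) / s
  list(x = matrix(v, s, s), y = matrix(v, s, s, byrow = TRUE))
}

# smooth elliptical head with a radial intensity falloff
.head_background <- function(g, cx, cy, rx, ry) {
  d2 <- ((g$x - cx) / rx) ^ 2 + ((g$y - cy) / ry) ^ 2
  inside <- 1 / (1 + exp((d2 - 1) * 18))  # soft edge
  inside * (0.45 - 0.18 * d2)
}

.gaussian_blob <- function(g, cx, cy, sd, amp) {
  amp * exp(-(((g$x - cx) ^ 2 + (g$y - cy) ^ 2) / (2 * sd ^ 2)))
}

# lesion field for one class; jitter entries perturb geometry per image
.lesion_field <- function(class_name, g, jitter) {
  j <- jitter
  switch(class_name,
    glioma = {  # large irregular off-center blob with diffuse edge
      cx <- 0.34 + j[1] * 0.015; cy <- 0.40 + j[2] * 0.015
      .gaussian_blob(g, cx, cy, 0.085 * (1 + 0.10 * j[3]), 0.45) +
        .gaussian_blob(g, cx + 0.07 + 0.01 * j[4], cy - 0.04, 0.060, 0.30) +
        .gaussian_blob(g, cx - 0.03, cy + 0.07 + 0.01 * j[5], 0.055, 0.28)
    },
    meningioma = {  # round bright peripheral blob
      ang <- pi / 4 + j[1] * 0.06
      cx <- 0.5 + 0.27 * cos(ang); cy <- 0.5 + 0.23 * sin(ang)
      .gaussian_blob(g, cx + 0.008 * j[2], cy + 0.008 * j[3],
                     0.055 * (1 + 0.08 * j[4]), 0.70)
    },
    pituitary = {  # small bright midline blob near the center
      .gaussian_blob(g, 0.5 + 0.008 * j[1], 0.56 + 0.008 * j[2],
                     0.035 * (1 + 0.08 * j[3]), 0.80)
    },
    notumor = matrix(0, nrow(g$x), ncol(g$x)),
    stop("unknown class: ", class_name))
}

#' Generate a reproducible synthetic 4-class image dataset
#'
#' Each image is a smooth elliptical "head" background plus a
#' class-specific lesion template with per-image geometric jitter, plus
#' Gaussian noise, clipped to [0, 1]. The templates are geometric
#' caricatures of the four appearances (glioma: large irregular off-center
#' diffuse blob; meningioma: round bright peripheral blob; pituitary: small
#' central bright blob; no-tumor: background only) — statistically
#' separable classes with a difficulty dial, not anatomy.
#'
#' @param params a [synthesis_params()].
#' @param split_tag `"train"` or `"test"` tag carried on the dataset.
#' @return Object of class `image_dataset`: `images` (`S x S x n` array in
#'   [0, 1]), `labels` (integer 0..3), `class_names`, `split_tag`.
#' @export
generate_dataset <- function(params = synthesis_params(), split_tag = "train") {
  stopifnot(inherits(params, "synthesis_params"))
  set.seed(params$seed)
  s <- params$image_size
  g <- .coord_grid(s)
  n_total <- sum(params$n_per_class)
  images <- array(0, dim = c(s, s, n_total))
  labels <- integer(n_total)
  # across-class mean of the canonical (unjittered) lesion templates
  canonical <- lapply(mri_class_names, .lesion_field, g = g, jitter = rep(0, 5))
  mean_lesion <- Reduce(`+`, canonical) / length(canonical)
  idx <- 0L
  for (ci in seq_along(mri_class_names)) {
    cls <- mri_class_names[ci]
    for (k in seq_len(params$n_per_class[ci])) {
      idx <- idx + 1L
      jitter <- stats::runif(5, -1, 1)
      bg <- .head_background(g,
                             cx = 0.5 + 0.002 * jitter[1],
                             cy = 0.5 + 0.002 * jitter[2],
                             rx = 0.40 * (1 + 0.006 * jitter[3]),
                             ry = 0.34 * (1 + 0.006 * jitter[4]))
      lesion <- .lesion_field(cls, g, stats::runif(5, -1, 1))
      a <- params$class_overlap
      lesion <- (1 - a) * lesion + a * mean_lesion
      img <- bg + lesion
      if (params$noise_sd > 0)
        img <- img + matrix(stats::rnorm(s * s, 0, params$noise_sd), s, s)
      images[, , idx] <- pmin(pmax(img, 0), 1)
      labels[idx] <- ci - 1L
    }
  }
  structure(list(images = images, labels = labels,
                 class_names = mri_class_names, split_tag = split_tag),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  cat(sprintf("image_dataset (%s): %d images %dx%d, classes: %s\n",
              x$split_tag, length(x$labels), dim(x$images)[1],
              dim(x$images)[2],
              paste(sprintf("%s=%d", x$class_names,
                            tabulate(x$labels + 1L, length(x$class_names))),
                    collapse = " ")))
  invisible(x)
}

# build an image_dataset from parts
.dataset <- function(images, labels, class_names, split_tag) {
  structure(list(images = images, labels = as.integer(labels),
                 class_names = class_names, split_tag = split_tag),
            class = "image_dataset")
}

#' Stratified train/test split of an image dataset
#'
#' @param data an `image_dataset`.
#' @param fraction fraction assigned to the first part.
#' @param seed optional integer seed.
#' @return List with `train` and `test` `image_dataset`s.
#' @export
split_dataset <- function(data, fraction = 0.8, seed = NULL) {
  stopifnot(inherits(data, "image_dataset"), fraction > 0, fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  take <- logical(length(data$labels))
  for (lev in unique(data$labels)) {
    ids <- which(data$labels == lev)
    n_take <- max(1L, round(fraction * length(ids)))
    take[sample(ids, n_take)] <- TRUE
  }
  list(train = .dataset(data$images[, , take, drop = FALSE], data$labels[take],
                        data$class_names, "train"),
       test = .dataset(data$images[, , !take, drop = FALSE], data$labels[!take],
                       data$class_names, "test"))
}

#' Rescale 8-bit intensities to [0, 1]
#'
#' Exact division by 255.
#'
#' @param image numeric matrix/array with values in [0, 255].
#' @return The image divided by 255.
#' @export
normalize_intensity <- function(image) {
  if (any(image < 0 | image > 255)) stop("intensities must lie in [0, 255]")
  image / 255
}

#' Randomly augment one image
#'
#' Horizontal flip with probability `flip_prob` (exact row reversal, an
#' involution), then a single composed affine map: rotation uniform in
#' `[-rotation_range, rotation_range]` degrees about the center, zoom
#' uniform in `[1 - zoom_range, 1 + zoom_range]`, and width/height shifts
#' uniform in `+/- shift_range` of the side length. Bilinear interpolation
#' (via EBImage) with background padding 0; output is clipped to [0, 1] and
#' keeps the input dimensions.
#'
#' @param image numeric matrix in [0, 1].
#' @param rotation_range degrees; 0 disables rotation.
#' @param flip_prob flip probability in [0, 1].
#' @param zoom_range relative zoom half-width; 0 disables zoom.
#' @param shift_range relative shift half-width; 0 disables shifts.
#' @return Augmented matrix of the same dimensions.
#' @export
augment_image <- function(image, rotation_range = 15, flip_prob = 0.5,
                          zoom_range = 0.1, shift_range = 0.1) {
  stopifnot(is.matrix(image))
  s <- dim(image)
  if (stats::runif(1) < flip_prob) image <- image[nrow(image):1, , drop = FALSE]
  angle <- stats::runif(1, -rotation_range, rotation_range) * pi / 180
  zoom <- stats::runif(1, 1 - zoom_range, 1 + zoom_range)
  shift <- stats::runif(2, -shift_range, shift_range) * s
  if (angle == 0 && zoom == 1 && all(shift == 0)) return(image)
  L <- zoom * matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  ctr <- (s + 1) / 2
  trans <- ctr + shift - as.vector(t(L) %*% ctr)
  m <- rbind(t(L), trans)  # EBImage forward-affine convention
  out <- EBImage::imageData(EBImage::affine(EBImage::Image(image), m,
                                            filter = "bilinear",
                                            output.dim = s, bg.col = 0,
                                            antialias = FALSE))
  pmin(pmax(matrix(out, s[1], s[2]), 0), 1)
}

#' Augment every image of a dataset
#'
#' @param data an `image_dataset`.
#' @param ... passed to [augment_image()].
#' @return The dataset with augmented images (labels unchanged).
#' @export
augment_dataset <- function(data, ...) {
  stopifnot(inherits(data, "image_dataset"))
  for (i in seq_len(dim(data$images)[3]))
    data$images[, , i] <- augment_image(data$images[, , i], ...)
  data
}

#' Encode class-name labels as integers or one-hot rows
#'
#' Classes are ordered alphabetically (stable across calls), giving integer
#' codes 0..3 or one-hot rows summing to 1.
#'
#' @param labels character vector of class names.
#' @param mode `"integer"` or `"one_hot"`.
#' @param class_names the full class set.
#' @return Integer vector or one-hot matrix.
#' @export
encode_labels <- function(labels, mode = c("integer", "one_hot"),
                          class_names = mri_class_names) {
  mode <- match.arg(mode)
  class_names <- sort(class_names)
  codes <- match(labels, class_names) - 1L
  if (anyNA(codes)) stop("unknown class name(s): ",
                         paste(unique(labels[is.na(codes)]), collapse = ", "))
  if (mode == "integer") codes else label_one_hot(codes, length(class_names))
}

#' Decode integer labels back to class names
#'
#' @param codes integer labels 0..C-1.
#' @param class_names the full class set (alphabetical order assumed).
#' @return Character vector.
#' @export
decode_labels <- function(codes, class_names = mri_class_names) {
  sort(class_names)[as.integer(codes) + 1L]
}

#' Read a class-subfolder image directory as an image dataset
#'
#' Expects one subdirectory per class (the Kaggle brain-tumor-mri-dataset
#' layout) of PNG/JPEG files; images are converted to grayscale (channel
#' mean), resized to `image_size` and kept in [0, 1].
#'
#' @param path directory containing one subdirectory per class.
#' @param image_size output side length.
#' @param split_tag tag for the returned dataset.
#' @return An `image_dataset`; classes are the sorted subdirectory names.
#' @export
read_image_dir <- function(path, image_size = 64L, split_tag = "train") {
  classes <- sort(list.dirs(path, full.names = FALSE, recursive = FALSE))
  if (length(classes) == 0L) stop("no class subdirectories under ", path)
  imgs <- list(); labels <- integer(0)
  for (ci in seq_along(classes)) {
    files <- sort(list.files(file.path(path, classes[ci]),
                             pattern = "\\.(png|jpg|jpeg)$",
                             ignore.case = TRUE, full.names = TRUE))
    for (f in files) {
      im <- EBImage::readImage(f)
      dat <- EBImage::imageData(im)
      if (length(dim(dat)) == 3L) dat <- apply(dat, c(1, 2), mean)
      im <- EBImage::resize(EBImage::Image(dat), w = image_size, h = image_size)
      imgs[[length(imgs) + 1L]] <- pmin(pmax(matrix(EBImage::imageData(im),
                                                    image_size, image_size), 0), 1)
      labels <- c(labels, ci - 1L)
    }
  }
  if (length(imgs) == 0L) stop("no images found under ", path)
  arr <- array(unlist(imgs), dim = c(image_size, image_size, length(imgs)))
  .dataset(arr, labels, classes, split_tag)
}

#' Write an image dataset to a class-subfolder PNG directory
#'
#' Inverse of [read_image_dir()]: the same folder reader then serves
#' synthetic and real data identically.
#'
#' @param data an `image_dataset`.
#' @param path output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_image_dir <- function(data, path) {
  stopifnot(inherits(data, "image_dataset"))
  paths <- character(0)
  counter <- integer(length(data$class_names))
  for (i in seq_len(dim(data$images)[3])) {
    ci <- data$labels[i] + 1L
    dir.create(file.path(path, data$class_names[ci]), recursive = TRUE,
               showWarnings = FALSE)
    counter[ci] <- counter[ci] + 1L
    f <- file.path(path, data$class_names[ci],
                   sprintf("%s_%05d.png", data$class_names[ci], counter[ci]))
    png::writePNG(t(data$images[, , i]), f)
    paths <- c(paths, f)
  }
  invisible(paths)
}
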