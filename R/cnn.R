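#' Build the CNN architecture from a hyperparameter configuration
#'
#' Fixed template: two 3x3 convolution blocks (stride 1, valid padding, ReLU,
#' 2x2 max-pool), flatten, a 128-unit dense hidden layer, dropout, and a
#' softmax output with one unit per class. The first block uses
#' `base_filters` filters and the second block twice as many (generalizing
#' the 32 -> 64 template); the dropout rate comes from the configuration.
#'
#' @param config a [cnn_config()].
#' @param input_size input side length in pixels (images are single-channel
#'   `input_size` x `input_size`).
#' @param n_classes number of output classes.
#' @param dense_units hidden dense layer width.
#' @return Object of class `cnn_architecture` including the exact layer
#'   dimensions and the trainable `param_count`.
#' @export
build_cnn <- function(config, input_size = 64L, n_classes = 4L,
                      dense_units = 128L) {
  stopifnot(inherits(config, "cnn_config"))
  if (config$base_filters < 1) stop("invalid filter count")
  f1 <- config$base_filters
  f2 <- 2L * f1
  c1 <- input_size - 2L
  q1 <- c1 %/% 2L
  c2 <- q1 - 2L
  q2 <- c2 %/% 2L
  if (q2 < 1L) stop("input size too small for two conv blocks")
  flat <- q2 * q2 * f2
  param_count <- (9L * 1L * f1 + f1) + (9L * f1 * f2 + f2) +
    (flat * dense_units + dense_units) + (dense_units * n_classes + n_classes)
  structure(list(conv1_filters = f1, conv2_filters = f2,
                 kernel_size = 3L, pool_size = 2L,
                 dense_units = as.integer(dense_units),
                 dropout_rate = config$dropout_rate,
                 n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 flat_units = flat,
                 param_count = param_count,
                 config = config),
            class = "cnn_architecture")
}

#' @export
print.cnn_architecture <- function(x, ...) {
  cat(sprintf(
    "CNN %dx%dx1: Conv(%d) ReLU MaxPool | Conv(%d) ReLU MaxPool | Dense(%d) Dropout(%.2f) Dense(%d) softmax [%s params]\n",
    x$input_size, x$input_size, x$conv1_filters, x$conv2_filters,
    x$dense_units, x$dropout_rate, x$n_classes,
    format(x$param_count, big.mark = ",")))
  invisible(x)
}

# images: 3-d array (S, S, n) or matrix (n, S^2); returns matrix (n, S^2)
.image_matrix <- function(images) {
  if (is.matrix(images)) return(images)
  if (length(dim(images)) != 3L) stop("images must be an S x S x n array")
  d <- dim(images)
  t(matrix(images, nrow = d[1] * d[2], ncol = d[3]))
}

#' Train the CNN
#'
#' Mini-batch training with the configured optimizer ("adam" or plain
#' "sgd"), learning rate and batch size; cross-entropy loss; inverted
#' dropout on the dense hidden layer. Deterministic given `seed`.
#'
#' @param config a [cnn_config()].
#' @param images training images: `S x S x n` array or `n x S^2` matrix of
#'   intensities in [0, 1].
#' @param labels integer class labels in `0..n_classes-1`.
#' @param epochs number of passes over the data.
#' @param input_size,n_classes,dense_units see [build_cnn()].
#' @param seed optional integer seed.
#' @param weights optional warm-start weights from a previous fit.
#' @return Object of class `cnn_model`: `weights`, `architecture`,
#'   `epoch_loss`.
#' @export
train_cnn <- function(config, images, labels, epochs = 3L,
                      input_size = 64L, n_classes = 4L, dense_units = 128L,
                      seed = NULL, weights = NULL) {
  stopifnot(epochs >= 1)
  arch <- build_cnn(config, input_size, n_classes, dense_units)
  X <- .image_matrix(images)
  labels <- as.integer(labels)
  if (any(labels < 0 | labels >= n_classes)) stop("labels must be in 0..n_classes-1")
  if (!is.null(seed)) set.seed(seed)
  fit <- cpp_cnn_train(X, labels, input_size, arch$conv1_filters,
                       dense_units, n_classes, config$learning_rate,
                       config$batch_size, config$dropout_rate,
                       config$optimizer_kind, as.integer(epochs),
                       weights)
  structure(list(weights = fit[c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")],
                 architecture = arch,
                 epoch_loss = fit$epoch_loss),
            class = "cnn_model")
}

#' Predict class probabilities with a trained CNN
#'
#' @param model a `cnn_model` from [train_cnn()].
#' @param images array or matrix as in [train_cnn()].
#' @return `n x n_classes` matrix of softmax probabilities (rows sum to 1).
#' @export
predict_cnn <- function(model, images) {
  stopifnot(inherits(model, "cnn_model"))
  cpp_cnn_predict(model$weights, .image_matrix(images),
                  model$architecture$input_size)
}

#' Multi-class cross-entropy loss
#'
#' Mean over samples of `-sum_i y_i * log(p_i)` with predicted
#' probabilities floored at `eps` before the log.
#'
#' @param y_true one-hot matrix (`n x C`) or integer labels in `0..C-1`.
#' @param y_pred `n x C` matrix of predicted probabilities; each row must
#'   sum to 1 within 1e-6.
#' @param eps probability floor.
#' @return Nonnegative scalar loss.
#' @export
cross_entropy <- function(y_true, y_pred, eps = 1e-12) {
  y_pred <- as.matrix(y_pred)
  if (!is.matrix(y_true)) {
    y_true <- label_one_hot(as.integer(y_true), ncol(y_pred))
  }
  if (!all(dim(y_true) == dim(y_pred))) stop("shape mismatch between y_true and y_pred")
  if (any(abs(rowSums(y_pred) - 1) > 1e-6)) stop("prediction rows must sum to 1")
  -mean(rowSums(y_true * log(pmax(y_pred, eps))))
}

# integer labels 0..C-1 -> one-hot matrix
label_one_hot <- function(labels, n_classes) {
  m <- matrix(0, length(labels), n_classes)
  m[cbind(seq_along(labels), labels + 1L)] <- 1
  m
}

#' Deterministic training-cost proxy
#'
#' Relative training cost built from the forward-pass complexity
#' `O(N * sum_i L_i * F_i^2)` per batch, with `N` the batch size, `L_i` the
#' filter counts of the two conv blocks and `F_i = 3` the kernel size:
#' `epochs * n_batches * N * sum(L_i * 9)`. Doubling the base filter count
#' doubles the proxy; it is a hardware-independent stand-in for wall-clock
#' training time in the composite objective.
#'
#' @param config a [cnn_config()].
#' @param n_train number of training samples per epoch.
#' @param epochs training epochs.
#' @return Nonnegative scalar in relative units.
#' @export
time_proxy <- function(config, n_train, epochs) {
  stopifnot(n_train >= 1, epochs >= 0)
  n_batches <- ceiling(n_train / config$batch_size)
  layer_cost <- sum(c(config$base_filters, 2L * config$base_filters) * 3 ^ 2)
  epochs * n_batches * config$batch_size * layer_cost
}

#' Largest time proxy over a search space
#'
#' Used to normalize the time term of the composite objective into [0, 1]:
#' the most expensive configuration in the space defines the unit.
#'
#' @param space a [hyperparameter_space()].
#' @inheritParams time_proxy
#' @return Positive scalar.
#' @export
max_time_proxy <- function(space, n_train, epochs) {
  grid <- expand.grid(batch = space$batch_choices, filters = space$filter_choices)
  max(mapply(function(b, f)
    time_proxy(cnn_config(space$learning_rate_range[2], b, f,
                          space$dropout_choices[1], space$optimizer_choices[1]),
               n_train, epochs),
    grid$batch, grid$filters))
}

#' Composite objective weights
#'
#' The candidate objective is `J = lambda1 * loss + lambda2 * time / T_max`,
#' trading validation cross-entropy against (normalized) training cost.
#' With `time_mode = "proxy"` the deterministic [time_proxy()] is used
#' (reproducible); `"measured"` uses wall-clock seconds (hardware
#' dependent).
#'
#' @param lambda1 weight of the validation loss (>= 0).
#' @param lambda2 weight of the normalized time term (>= 0).
#' @param time_normalizer positive `T_max`; `NULL` auto-computes the proxy
#'   of the most expensive configuration in the default space.
#' @param time_mode `"proxy"` or `"measured"`.
#' @return Object of class `objective_weights`.
#' @export
objective_weights <- function(lambda1 = 1.0, lambda2 = 0.1,
                              time_normalizer = NULL,
                              time_mode = c("proxy", "measured")) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, lambda1 + lambda2 > 0)
  time_mode <- match.arg(time_mode)
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 time_normalizer = time_normalizer, time_mode = time_mode),
            class = "objective_weights")
}

#' Train and score one hyperparameter candidate
#'
#' Splits the supplied data into training and validation parts (stratified
#' by class, fixed by `seed`), trains [build_cnn()] under the candidate
#' configuration, and returns the validation cross-entropy, the time
#' measure, the composite objective `J`, the macro metrics and the
#' validation confusion matrix. A non-finite validation loss (diverged
#' training) is replaced by a large finite penalty so the optimizer can
#' continue, with a warning.
#'
#' @param config a [cnn_config()].
#' @param data an `image_dataset` (see [generate_dataset()]).
#' @param weights an [objective_weights()].
#' @param train_epochs epochs per evaluation (small during tuning).
#' @param seed integer seed controlling the split and the training run.
#' @param validation_fraction held-out fraction for the validation loss.
#' @return Object of class `evaluation_result` with fields `loss`,
#'   `time_measure`, `objective`, `metrics`, `confusion`, `model`.
#' @export
evaluate_candidate <- function(config, data, weights = objective_weights(),
                               train_epochs = 3L, seed = NULL,
                               validation_fraction = 0.2) {
  stopifnot(inherits(config, "cnn_config"), train_epochs >= 1)
  if (!is.null(seed)) {
    # localize the seeded section so callers' RNG streams are undisturbed
    if (exists(".Random.seed", globalenv())) {
      old_seed <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    }
  }
  sp <- split_dataset(data, fraction = 1 - validation_fraction, seed = seed)
  train <- sp$train
  val <- sp$test
  n_train <- length(train$labels)
  t0 <- proc.time()[["elapsed"]]
  model <- train_cnn(config, train$images, train$labels, epochs = train_epochs,
                     input_size = dim(train$images)[1],
                     n_classes = length(data$class_names), seed = seed)
  elapsed <- proc.time()[["elapsed"]] - t0
  probs <- predict_cnn(model, val$images)
  loss <- cross_entropy(val$labels, probs)
  tm <- if (weights$time_mode == "proxy") {
    time_proxy(config, n_train, train_epochs)
  } else elapsed
  t_max <- weights$time_normalizer
  if (is.null(t_max)) {
    t_max <- if (weights$time_mode == "proxy") {
      max_time_proxy(hyperparameter_space(), n_train, train_epochs)
    } else max(elapsed, 1)
  }
  if (!is.finite(loss)) {
    warning("non-finite validation loss for ", format(config),
            "; assigning penalty objective")
    loss <- NA_real_
    objective <- 1e6
  } else {
    objective <- weights$lambda1 * loss + weights$lambda2 * tm / t_max
  }
  pred <- max.col(probs) - 1L
  cm <- confusion_matrix(val$labels, pred, class_names = data$class_names)
  structure(list(loss = loss, time_measure = tm, objective = objective,
                 metrics = compute_metrics(cm), confusion = cm,
                 model = model, config = config),
            class = "evaluation_result")
}

#' Confusion matrix with fixed class set
#'
#' Rows are true classes, columns predicted classes; zero-count classes are
#' kept so the matrix is always `C x C`.
#'
#' @param true,pred integer labels in `0..C-1`.
#' @param class_names class names in label order.
#' @return Integer matrix of class `confusion_matrix` with dimnames.
#' @export
confusion_matrix <- function(true, pred, class_names) {
  k <- length(class_names)
  lev <- 0:(k - 1)
  m <- as.matrix(table(factor(true, levels = lev), factor(pred, levels = lev)))
  dimnames(m) <- list(true = class_names, predicted = class_names)
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is the trace over the total. Precision, recall and F1 are
#' computed per class by one-vs-rest reduction (TP, FP, FN) and
#' macro-averaged (classes weighted equally). A class never predicted
#' contributes precision 0 (reported via a message).
#'
#' @param confusion a square count matrix, rows = true, columns = predicted.
#' @return List with `accuracy`, `precision`, `recall`, `f1` and a
#'   `per_class` data.frame.
#' @export
compute_metrics <- function(confusion) {
  m <- unclass(as.matrix(confusion))
  if (nrow(m) != ncol(m) || sum(m) == 0) stop("confusion matrix must be square and non-empty")
  total <- sum(m)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  predicted <- tp + fp
  if (any(predicted == 0))
    message("class(es) with zero predicted positives: precision set to 0")
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(accuracy = sum(tp) / total,
       precision = mean(precision),
       recall = mean(recall),
       f1 = mean(f1),
       per_class = data.frame(class = rownames(m) %||% as.character(seq_len(nrow(m)) - 1L),
                              precision = unname(precision),
                              recall = unname(recall),
                              f1 = unname(f1),
                              support = unname(rowSums(m)),
                              stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
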