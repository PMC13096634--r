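test_that("the architecture follows the two-block template", {
  a <- build_cnn(cnn_config(1e-3, 32L, 32L, 0.5, "adam"))
  expect_equal(a$conv1_filters, 32L)
  expect_equal(a$conv2_filters, 64L)
  expect_equal(a$dense_units, 128L)
  expect_equal(a$dropout_rate, 0.5)
  expect_equal(a$n_classes, 4L)
  b <- build_cnn(cnn_config(1e-3, 32L, 128L, 0.3, "sgd"))
  expect_equal(c(b$conv1_filters, b$conv2_filters), c(128L, 256L))
  expect_error(build_cnn(cnn_config(1e-3, 32L, 32L, 0.5, "adam"),
                         input_size = 8), "too small")
})

test_that("the parameter count matches an independent weight-count computation", {
  # valid 3x3 convs, 2x2 pools: 64 -> 62 -> 31 -> 29 -> 14
  f1 <- 32; f2 <- 64; flat <- 14 * 14 * f2
  by_hand <- (3 * 3 * 1 * f1 + f1) + (3 * 3 * f1 * f2 + f2) +
    (flat * 128 + 128) + (128 * 4 + 4)
  expect_equal(build_cnn(cnn_config(1e-3, 32L, 32L, 0.5, "adam"))$param_count,
               by_hand)
  expect_equal(by_hand, 1625092)
})

test_that("cross-entropy has its analytic values and guards", {
  perfect <- diag(4)
  expect_equal(cross_entropy(perfect, perfect), 0)
  uniform <- matrix(0.25, 3, 4)
  truth <- label_one_hot(c(0L, 1L, 3L), 4)
  expect_equal(cross_entropy(truth, uniform), log(4))
  expect_equal(cross_entropy(matrix(c(1, 0, 0, 0), 1),
                             matrix(c(0.7, 0.1, 0.1, 0.1), 1)),
               -log(0.7))
  expect_error(cross_entropy(diag(4), matrix(0.25, 3, 4)), "shape")
  expect_error(cross_entropy(diag(4), matrix(0.3, 4, 4)), "sum to 1")
  # integer-label interface agrees with the one-hot interface
  p <- matrix(c(0.6, 0.2, 0.1, 0.1,
                0.1, 0.7, 0.1, 0.1), 2, 4, byrow = TRUE)
  expect_equal(cross_entropy(c(0L, 1L), p),
               cross_entropy(label_one_hot(c(0L, 1L), 4), p))
})

test_that("the time proxy is linear in filters and matches direct substitution", {
  cfg32 <- cnn_config(1e-3, 16L, 32L, 0.5, "adam")
  cfg64 <- cnn_config(1e-3, 16L, 64L, 0.5, "adam")
  expect_equal(time_proxy(cfg64, 160, 3), 2 * time_proxy(cfg32, 160, 3))
  expect_equal(time_proxy(cfg32, 160, 0), 0)
  # per-batch cost: N * (32*9 + 64*9) = N * 864, times epochs * n_batches
  n_batches <- ceiling(160 / 16)
  expect_equal(time_proxy(cfg32, 160, 3), 3 * n_batches * 16 * 864)
  # the normalizer is attained by the most expensive configuration
  expect_equal(max_time_proxy(hyperparameter_space(), 160, 3),
               time_proxy(cnn_config(1e-2, 64L, 128L, 0.5, "adam"), 160, 3))
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  n <- 5; S <- 16
  X <- matrix(runif(n * S * S), n, S * S)
  y <- c(0L, 1L, 2L, 3L, 1L)
  m <- train_cnn(cnn_config(1e-3, 4L, 4L, 0.3, "sgd"), X, y, epochs = 1,
                 input_size = S, dense_units = 8, seed = 1)
  lg <- aohho:::cpp_cnn_loss_grad(m$weights, X, y, S)
  w <- m$weights
  eps <- 1e-5
  for (nm in names(w)) {
    g <- lg[[paste0("g", nm)]]
    ids <- sample(length(w[[nm]]), min(4, length(w[[nm]])))
    for (i in ids) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (aohho:::cpp_cnn_loss_grad(wp, X, y, S)$loss -
                aohho:::cpp_cnn_loss_grad(wm, X, y, S)$loss) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-5)
    }
  }
})

test_that("training is seed-reproducible and predictions are probabilities", {
  ds <- tiny_dataset()
  cfg <- cnn_config(1e-3, 8L, 32L, 0.5, "adam")
  m1 <- train_cnn(cfg, ds$images, ds$labels, epochs = 2, seed = 5)
  m2 <- train_cnn(cfg, ds$images, ds$labels, epochs = 2, seed = 5)
  expect_identical(m1$weights, m2$weights)
  p <- predict_cnn(m1, ds$images)
  expect_equal(dim(p), c(length(ds$labels), 4L))
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-5)
  expect_length(m1$epoch_loss, 2)
})

test_that("a well-conditioned configuration fits separable data quickly", {
  ds <- generate_dataset(synthesis_params(n_per_class = rep(50L, 4),
                                          noise_sd = 0, class_overlap = 0,
                                          seed = 9))
  ev <- suppressMessages(
    evaluate_candidate(cnn_config(1e-4, 16L, 32L, 0.3, "adam"), ds,
                       train_epochs = 5, seed = 3))
  expect_lt(ev$loss, 0.3)
  expect_equal(ev$metrics$accuracy, 1)
})

test_that("the composite objective weights loss against normalized time", {
  ds <- tiny_dataset()
  cfg <- cnn_config(1e-3, 8L, 32L, 0.3, "adam")
  only_loss <- suppressMessages(
    evaluate_candidate(cfg, ds, objective_weights(lambda1 = 1, lambda2 = 0),
                       train_epochs = 1, seed = 2))
  expect_equal(only_loss$objective, only_loss$loss)
  only_time <- suppressMessages(
    evaluate_candidate(cfg, ds, objective_weights(lambda1 = 0, lambda2 = 1),
                       train_epochs = 1, seed = 2))
  n_train <- length(ds$labels) - sum(only_time$confusion)
  expect_equal(only_time$objective,
               only_time$time_measure /
                 max_time_proxy(hyperparameter_space(), n_train, 1))
  # J is monotone in both terms for fixed weights
  w <- objective_weights(1, 0.1, time_normalizer = 100)
  expect_lt(1 * 0.5 + 0.1 * 10 / 100, 1 * 0.6 + 0.1 * 10 / 100)
  expect_lt(1 * 0.5 + 0.1 * 10 / 100, 1 * 0.5 + 0.1 * 20 / 100)
  # proxy-mode evaluation is reproducible
  expect_equal(only_loss$objective,
               suppressMessages(evaluate_candidate(
                 cfg, ds, objective_weights(lambda1 = 1, lambda2 = 0),
                 train_epochs = 1, seed = 2))$objective)
})

test_that("metrics follow the one-vs-rest definitions", {
  cm <- confusion_matrix(rep(0:3, each = 5), rep(0:3, each = 5), letters[1:4])
  m <- compute_metrics(cm)
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # hand-computed 2-class example
  m2 <- compute_metrics(matrix(c(50, 10, 5, 35), 2, byrow = TRUE))
  expect_equal(m2$accuracy, 0.85)
  expect_equal(m2$per_class$precision[1], 50 / 55)
  expect_equal(m2$per_class$recall[1], 50 / 60)
  hand <- metrics_by_hand(matrix(c(50, 10, 5, 35), 2, byrow = TRUE))
  expect_equal(m2$f1, hand$f1)
  # the no-tumor row of the reported confusion matrix: 393 of 405 correct
  expect_equal(393 / 405, 0.97037, tolerance = 1e-5)
  cm4 <- matrix(c(393, 4, 5, 3,
                  6, 290, 6, 4,
                  5, 4, 288, 3,
                  2, 3, 4, 291), 4, byrow = TRUE)
  expect_equal(compute_metrics(cm4)$per_class$recall[1], 393 / 405)
  expect_error(compute_metrics(matrix(0, 2, 2)), "non-empty")
})

test_that("a never-predicted class yields precision 0 with a message", {
  cm <- matrix(c(5, 0, 0,
                 5, 0, 0,
                 0, 0, 5), 3, byrow = TRUE)
  expect_message(m <- compute_metrics(cm), "zero predicted")
  expect_equal(m$per_class$precision[2], 0)
})

test_that("accuracy equals the support-weighted average of per-class recall", {
  set.seed(31)
  for (rep in 1:20) {
    cm <- matrix(rpois(16, 20), 4, 4)
    m <- compute_metrics(cm)
    support <- rowSums(cm)
    expect_equal(m$accuracy,
                 sum(m$per_class$recall * support) / sum(support))
  }
})
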