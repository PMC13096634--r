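# shared helpers: small fixtures and independent oracle computations

# nearest class-mean (Euclidean) template classifier; independent of the CNN
nearest_template_predict <- function(train, test) {
  means <- lapply(sort(unique(train$labels)), function(cl)
    apply(train$images[, , train$labels == cl, drop = FALSE], c(1, 2), mean))
  vapply(seq_len(dim(test$images)[3]), function(i) {
    d <- vapply(means, function(m) sum((m - test$images[, , i]) ^ 2), numeric(1))
    which.min(d) - 1L
  }, integer(1))
}

# independent arithmetic route to the macro metrics of a confusion matrix
metrics_by_hand <- function(m) {
  k <- nrow(m)
  prec <- rec <- f1 <- numeric(k)
  for (i in seq_len(k)) {
    tp <- m[i, i]
    prec[i] <- if (sum(m[, i]) > 0) tp / sum(m[, i]) else 0
    rec[i] <- if (sum(m[i, ]) > 0) tp / sum(m[i, ]) else 0
    f1[i] <- if (prec[i] + rec[i] > 0) 2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  list(accuracy = sum(diag(m)) / sum(m),
       precision = mean(prec), recall = mean(rec), f1 = mean(f1))
}

# a tiny balanced synthetic dataset for CNN unit tests
tiny_dataset <- function(n_per_class = 8L, seed = 101L, noise_sd = 0.02) {
  generate_dataset(synthesis_params(n_per_class = rep(n_per_class, 4L),
                                    noise_sd = noise_sd, class_overlap = 0,
                                    seed = seed))
}

sphere_fn <- function(x) sum(x ^ 2)
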