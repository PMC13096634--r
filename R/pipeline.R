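#' End-to-end pipeline: tune hyperparameters, refit, evaluate on test data
#'
#' Runs the full protocol: AO-HHO (or AO/HHO alone) searches the
#' hyperparameter space, scoring each candidate by the composite objective
#' on a stratified train/validation split of `train_data`; the best
#' configuration is then refit on all of `train_data` (more epochs than
#' during tuning) and evaluated once on `test_data`.
#'
#' Candidate evaluations are seeded with `config$seed + 1` (localized, so
#' the optimizer's own RNG stream is not disturbed), making the whole
#' pipeline a deterministic function of the data and `config$seed`.
#'
#' @param train_data,test_data `image_dataset`s with the same classes.
#' @param space a [hyperparameter_space()].
#' @param config a [hybrid_config()]; its `seed` drives the whole run.
#' @param weights an [objective_weights()].
#' @param tune_epochs training epochs per candidate evaluation.
#' @param refit_epochs training epochs for the final refit.
#' @param method `"aohho"`, `"ao"` or `"hho"`.
#' @param params an [ao_params()].
#' @return Object of class `aohho_pipeline`: `optimization`
#'   (an `aohho_result`), `model`, `confusion`, `metrics`, `test_loss`.
#' @export
run_pipeline <- function(train_data, test_data,
                         space = hyperparameter_space(),
                         config = hybrid_config(),
                         weights = objective_weights(),
                         tune_epochs = 3L, refit_epochs = 8L,
                         method = c("aohho", "ao", "hho"),
                         params = ao_params()) {
  method <- match.arg(method)
  stopifnot(inherits(train_data, "image_dataset"),
            inherits(test_data, "image_dataset"))
  eval_seed <- if (!is.null(config$seed)) config$seed + 1L else NULL
  fitness_fn <- function(cfg)
    evaluate_candidate(cfg, train_data, weights, tune_epochs,
                       seed = eval_seed)$objective
  opt <- ao_hho_optimize(fitness_fn, space, config, method = method,
                         params = params)
  best <- opt$best_config
  model <- train_cnn(best, train_data$images, train_data$labels,
                     epochs = refit_epochs,
                     input_size = dim(train_data$images)[1],
                     n_classes = length(train_data$class_names),
                     seed = eval_seed)
  probs <- predict_cnn(model, test_data$images)
  pred <- max.col(probs) - 1L
  cm <- confusion_matrix(test_data$labels, pred, test_data$class_names)
  structure(list(optimization = opt, model = model, confusion = cm,
                 metrics = compute_metrics(cm),
                 test_loss = cross_entropy(test_data$labels, probs)),
            class = "aohho_pipeline")
}

#' @export
print.aohho_pipeline <- function(x, ...) {
  cat("AO-HHO CNN pipeline\n")
  print(x$optimization$best_config)
  m <- x$metrics
  cat(sprintf("  test accuracy %.4f | macro precision %.4f | recall %.4f | F1 %.4f\n",
              m$accuracy, m$precision, m$recall, m$f1))
  invisible(x)
}

#' Metric vector of a pipeline run, for [repeated_runs()]
#'
#' @param pipeline_result an `aohho_pipeline`.
#' @return Named numeric vector (accuracy, precision, recall, f1,
#'   objective).
#' @export
pipeline_metrics <- function(pipeline_result) {
  m <- pipeline_result$metrics
  c(accuracy = m$accuracy, precision = m$precision, recall = m$recall,
    f1 = m$f1, objective = pipeline_result$optimization$best_objective)
}
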