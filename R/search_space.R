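#' Mixed hyperparameter search space
#'
#' Describes the tuned CNN hyperparameters: a continuous learning-rate range
#' and four categorical choices (batch size, base filter count, dropout rate,
#' optimizer kind). The defaults are the standard space used for compact
#' medical-image CNNs: learning rate in [1e-4, 1e-2], batch size
#' {16, 32, 64}, filters {32, 64, 128}, dropout {0.3, 0.5}, optimizer
#' {adam, sgd}.
#'
#' Internally the optimizers search the unit hypercube [0,1]^5; see
#' [decode_config()] / [encode_config()] for the mapping.
#'
#' @param learning_rate_range numeric length-2, positive, increasing.
#' @param batch_choices sorted positive integers.
#' @param filter_choices sorted positive integers (filters of the first
#'   convolutional block; the second block uses twice as many).
#' @param dropout_choices sorted reals in (0, 1).
#' @param optimizer_choices character vector of optimizer names.
#' @return An object of class `hyperparameter_space`.
#' @export
hyperparameter_space <- function(learning_rate_range = c(1e-4, 1e-2),
                                 batch_choices = c(16L, 32L, 64L),
                                 filter_choices = c(32L, 64L, 128L),
                                 dropout_choices = c(0.3, 0.5),
                                 optimizer_choices = c("adam", "sgd")) {
  stopifnot(length(learning_rate_range) == 2L,
            all(learning_rate_range > 0),
            learning_rate_range[1] < learning_rate_range[2],
            length(batch_choices) >= 1L, !is.unsorted(batch_choices),
            length(filter_choices) >= 1L, !is.unsorted(filter_choices),
            length(dropout_choices) >= 1L, !is.unsorted(dropout_choices),
            all(dropout_choices > 0 & dropout_choices < 1),
            length(optimizer_choices) >= 1L)
  structure(list(learning_rate_range = as.numeric(learning_rate_range),
                 batch_choices = as.integer(batch_choices),
                 filter_choices = as.integer(filter_choices),
                 dropout_choices = as.numeric(dropout_choices),
                 optimizer_choices = as.character(optimizer_choices)),
            class = "hyperparameter_space")
}

#' Read a hyperparameter space from a YAML/JSON-style list
#'
#' Accepts a list with any of the keys `learning_rate` (length-2 range),
#' `batch_size`, `filters`, `dropout`, `optimizer`; missing keys keep their
#' defaults.
#'
#' @param cfg a named list, e.g. parsed from a YAML config file.
#' @return A `hyperparameter_space`.
#' @export
space_from_config <- function(cfg) {
  stopifnot(is.list(cfg))
  d <- hyperparameter_space()
  hyperparameter_space(
    learning_rate_range = if (!is.null(cfg$learning_rate)) as.numeric(cfg$learning_rate) else d$learning_rate_range,
    batch_choices = if (!is.null(cfg$batch_size)) as.integer(cfg$batch_size) else d$batch_choices,
    filter_choices = if (!is.null(cfg$filters)) as.integer(cfg$filters) else d$filter_choices,
    dropout_choices = if (!is.null(cfg$dropout)) as.numeric(cfg$dropout) else d$dropout_choices,
    optimizer_choices = if (!is.null(cfg$optimizer)) as.character(cfg$optimizer) else d$optimizer_choices)
}

#' Box bounds for the optimizer-internal real vectors
#'
#' @param dimension positive integer; 5 for the default CNN space.
#' @param lower,upper scalars or vectors of length `dimension`.
#' @return An object of class `search_bounds` with fields `lower`, `upper`,
#'   `dimension`.
#' @export
search_bounds <- function(dimension = 5L, lower = 0, upper = 1) {
  dimension <- as.integer(dimension)
  stopifnot(dimension >= 1L)
  lower <- rep_len(as.numeric(lower), dimension)
  upper <- rep_len(as.numeric(upper), dimension)
  if (!all(lower < upper)) stop("each lower bound must be < its upper bound")
  structure(list(lower = lower, upper = upper, dimension = dimension),
            class = "search_bounds")
}

#' CNN hyperparameter configuration
#'
#' @param learning_rate positive real.
#' @param batch_size positive integer.
#' @param base_filters positive integer (first conv block; second uses 2x).
#' @param dropout_rate real in (0, 1).
#' @param optimizer_kind optimizer name ("adam" or "sgd" by default).
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(learning_rate, batch_size, base_filters,
                       dropout_rate, optimizer_kind) {
  stopifnot(is.numeric(learning_rate), learning_rate > 0,
            batch_size >= 1, base_filters >= 1,
            dropout_rate > 0, dropout_rate < 1,
            is.character(optimizer_kind), length(optimizer_kind) == 1L)
  structure(list(learning_rate = as.numeric(learning_rate),
                 batch_size = as.integer(batch_size),
                 base_filters = as.integer(base_filters),
                 dropout_rate = as.numeric(dropout_rate),
                 optimizer_kind = optimizer_kind),
            class = "cnn_config")
}

#' @export
print.cnn_config <- function(x, ...) {
  cat(sprintf(
    "CNN config: lr=%.5g batch=%d filters=%d dropout=%.2f optimizer=%s\n",
    x$learning_rate, x$batch_size, x$base_filters, x$dropout_rate,
    x$optimizer_kind))
  invisible(x)
}

# equal-width bin index (0-based) on [0,1] with u = 1 mapped to the last bin
.bin_index <- function(u, k) pmin(floor(u * k), k - 1L)

#' Decode a unit-hypercube vector into a CNN configuration
#'
#' The learning rate is decoded log-uniformly over its range (the range spans
#' two decades, so a linear map would under-sample small rates); each
#' categorical coordinate is decoded by equal-width binning of [0,1] into as
#' many bins as there are choices, with a coordinate of exactly 1 mapping to
#' the last bin. Coordinate order: learning rate, batch size, filters,
#' dropout, optimizer.
#'
#' @param u numeric vector in [0,1]^5 (callers must clip first, see
#'   [clip_to_bounds()]).
#' @param space a [hyperparameter_space()].
#' @return A [cnn_config()].
#' @export
decode_config <- function(u, space = hyperparameter_space()) {
  stopifnot(inherits(space, "hyperparameter_space"))
  if (length(u) != 5L) stop("decode_config expects a vector of dimension 5")
  if (any(u < 0 | u > 1)) stop("components must lie in [0,1]; clip first")
  lr <- 10 ^ (log10(space$learning_rate_range[1]) +
                u[1] * diff(log10(space$learning_rate_range)))
  cnn_config(
    learning_rate = lr,
    batch_size = space$batch_choices[.bin_index(u[2], length(space$batch_choices)) + 1L],
    base_filters = space$filter_choices[.bin_index(u[3], length(space$filter_choices)) + 1L],
    dropout_rate = space$dropout_choices[.bin_index(u[4], length(space$dropout_choices)) + 1L],
    optimizer_kind = space$optimizer_choices[.bin_index(u[5], length(space$optimizer_choices)) + 1L])
}

#' Encode a CNN configuration as a unit-hypercube vector
#'
#' Inverse of [decode_config()]: categorical values map to the centers of
#' their bins, the learning rate to its log-scale position, so that
#' `decode_config(encode_config(c)) == c` for every valid configuration.
#'
#' @param config a [cnn_config()].
#' @param space a [hyperparameter_space()].
#' @return Numeric vector of length 5 in [0,1].
#' @export
encode_config <- function(config, space = hyperparameter_space()) {
  stopifnot(inherits(config, "cnn_config"), inherits(space, "hyperparameter_space"))
  rng <- space$learning_rate_range
  if (config$learning_rate < rng[1] || config$learning_rate > rng[2])
    stop("learning rate outside the space's range")
  center <- function(value, choices) {
    i <- match(value, choices)
    if (is.na(i)) stop("configuration value ", value, " is not among the choices")
    (i - 0.5) / length(choices)
  }
  c((log10(config$learning_rate) - log10(rng[1])) / diff(log10(rng)),
    center(config$batch_size, space$batch_choices),
    center(config$base_filters, space$filter_choices),
    center(config$dropout_rate, space$dropout_choices),
    center(config$optimizer_kind, space$optimizer_choices))
}

#' Clamp a vector into box bounds
#'
#' AO/HHO position updates can leave the box; every proposed position is
#' clamped component-wise back into [lower, upper]. Idempotent.
#'
#' @param x numeric vector of length `bounds$dimension`.
#' @param bounds a [search_bounds()].
#' @return The clamped vector.
#' @export
clip_to_bounds <- function(x, bounds) {
  if (length(x) != bounds$dimension) stop("dimension mismatch")
  pmin(pmax(x, bounds$lower), bounds$upper)
}

#' Sample an initial population uniformly within bounds
#'
#' @param n population size (at least 2: the AO mean position and the HHO
#'   rabbit/hawk roles need a second agent).
#' @param bounds a [search_bounds()].
#' @param seed optional integer; when given, seeds R's RNG for
#'   reproducibility.
#' @return A list of `n` numeric vectors.
#' @export
sample_population <- function(n, bounds, seed = NULL) {
  if (n < 2) stop("population size must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i)
    bounds$lower + stats::runif(bounds$dimension) * (bounds$upper - bounds$lower))
}
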