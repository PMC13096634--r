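#' Hybrid optimizer run configuration
#'
#' @param population_size number of agents P (>= 2).
#' @param max_iterations iteration budget I (>= 2).
#' @param switch_fraction fraction of iterations run with AO before the
#'   elitist hand-off to HHO (a single hard switch at
#'   `ceiling(switch_fraction * I)`).
#' @param epsilon convergence threshold on successive best-objective changes.
#' @param patience number of successive sub-epsilon changes required to stop
#'   early.
#' @param seed integer seed for the run's single RNG stream (`NULL` keeps the
#'   current stream).
#' @return Object of class `hybrid_config`.
#' @export
hybrid_config <- function(population_size = 10L, max_iterations = 20L,
                          switch_fraction = 0.5, epsilon = 1e-4,
                          patience = 10L, seed = NULL) {
  stopifnot(population_size >= 2, max_iterations >= 2,
            switch_fraction >= 0, switch_fraction <= 1,
            epsilon > 0, patience >= 1)
  structure(list(population_size = as.integer(population_size),
                 max_iterations = as.integer(max_iterations),
                 switch_fraction = switch_fraction,
                 epsilon = epsilon, patience = as.integer(patience),
                 seed = seed),
            class = "hybrid_config")
}

#' Convergence test on the best-objective trace
#'
#' Converged when the last `patience` successive absolute changes are all
#' below `epsilon`. Traces shorter than `patience + 1` are never converged.
#'
#' @param history numeric vector of best objective values per iteration.
#' @param epsilon positive threshold.
#' @param patience integer >= 1.
#' @return Logical flag.
#' @export
check_convergence <- function(history, epsilon, patience) {
  stopifnot(epsilon > 0, patience >= 1)
  if (length(history) < patience + 1L) return(FALSE)
  all(abs(diff(utils::tail(history, patience + 1L))) < epsilon)
}

#' Run AO, HHO or the AO-HHO hybrid on a vector objective
#'
#' The core population driver: AO iterations for
#' `t = 1..ceiling(switch_fraction * I)`, then the full population and the
#' incumbent best are handed to HHO unchanged for the remaining iterations
#' (elitist hand-off, no re-initialization). `method = "ao"` and `"hho"`
#' are the degenerate switch fractions 1 and 0, so an AO-only run is
#' bit-identical to the hybrid with `switch_fraction = 1` under the same
#' seed.
#'
#' @param fn objective: function from a numeric vector to a finite scalar
#'   (minimized).
#' @param bounds a [search_bounds()].
#' @param method `"aohho"`, `"ao"` or `"hho"`.
#' @param config a [hybrid_config()].
#' @param params an [ao_params()].
#' @param early_stop apply [check_convergence()] each iteration.
#' @return List with `best_position`, `best_fitness`, `history` (data.frame
#'   with iteration, phase, best_objective), `evaluations`,
#'   `converged_early`, and the final `state`.
#' @export
run_optimizer <- function(fn, bounds, method = c("aohho", "ao", "hho"),
                          config = hybrid_config(), params = ao_params(),
                          early_stop = TRUE) {
  method <- match.arg(method)
  if (!is.null(config$seed)) set.seed(config$seed)
  n_eval <- 0L
  counted_fn <- function(x) {
    n_eval <<- n_eval + 1L
    v <- fn(x)
    if (!is.finite(v)) stop("objective returned a non-finite value")
    v
  }
  pop <- sample_population(config$population_size, bounds)
  fits <- vapply(pop, counted_fn, numeric(1))
  state <- optimizer_state(pop, fits, config$max_iterations)
  I <- config$max_iterations
  switch_iter <- switch(method,
                        aohho = ceiling(config$switch_fraction * I),
                        ao = I, hho = 0L)
  phases <- character(0)
  converged <- FALSE
  while (state$iteration <= I) {
    phase <- if (state$iteration <= switch_iter) "AO" else "HHO"
    state <- if (phase == "AO") {
      ao_iteration(state, params, bounds, counted_fn)
    } else {
      hho_iteration(state, bounds, counted_fn, params)
    }
    phases <- c(phases, phase)
    if (early_stop && check_convergence(state$history, config$epsilon,
                                        config$patience)) {
      converged <- TRUE
      break
    }
  }
  list(best_position = state$best_position,
       best_fitness = state$best_fitness,
       history = data.frame(iteration = seq_along(state$history),
                            phase = phases,
                            best_objective = state$history,
                            stringsAsFactors = FALSE),
       evaluations = n_eval,
       converged_early = converged,
       state = state)
}

#' Tune CNN hyperparameters with the AO-HHO hybrid
#'
#' Wraps [run_optimizer()] for a configuration-level objective: optimizer
#' vectors in `[0,1]^5` are clipped, decoded into CNN configurations
#' ([decode_config()]) and scored by `fitness_fn`. A fitness cache keyed by
#' the decoded configuration serves duplicate configurations without
#' re-evaluation, so categorical plateaus do not trigger redundant CNN
#' trainings; `evaluations_used` counts cache misses (actual trainings).
#'
#' @param fitness_fn function mapping a [cnn_config()] to a finite scalar
#'   objective (lower is better), e.g. built from [evaluate_candidate()].
#' @param space a [hyperparameter_space()].
#' @param config a [hybrid_config()].
#' @param method `"aohho"` (default), `"ao"` or `"hho"`.
#' @param params an [ao_params()].
#' @return Object of class `aohho_result`: `best_config`, `best_objective`,
#'   `history`, `evaluations_used`, `converged_early`.
#' @export
ao_hho_optimize <- function(fitness_fn, space = hyperparameter_space(),
                            config = hybrid_config(),
                            method = c("aohho", "ao", "hho"),
                            params = ao_params()) {
  method <- match.arg(method)
  stopifnot(inherits(config, "hybrid_config"))
  cache <- new.env(parent = emptyenv())
  misses <- 0L
  bounds <- search_bounds(5L)
  vec_fn <- function(u) {
    cfg <- decode_config(clip_to_bounds(u, bounds), space)
    key <- paste(format(cfg$learning_rate, digits = 15), cfg$batch_size,
                 cfg$base_filters, cfg$dropout_rate, cfg$optimizer_kind,
                 sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- tryCatch(fitness_fn(cfg), error = function(e)
      stop("candidate evaluation failed for ", format(cfg), ": ",
           conditionMessage(e), call. = FALSE))
    misses <<- misses + 1L
    cache[[key]] <- val
    val
  }
  res <- run_optimizer(vec_fn, bounds, method, config, params)
  structure(list(best_config = decode_config(clip_to_bounds(res$best_position, bounds), space),
                 best_objective = res$best_fitness,
                 best_position = res$best_position,
                 history = res$history,
                 evaluations_used = misses,
                 converged_early = res$converged_early),
            class = "aohho_result")
}

#' @export
print.aohho_result <- function(x, ...) {
  cat("AO-HHO optimization result\n")
  cat(sprintf("  best objective: %.6g after %d evaluations (%s)\n",
              x$best_objective, x$evaluations_used,
              if (x$converged_early) "converged early" else "budget exhausted"))
  print(x$best_config)
  invisible(x)
}

#' @export
format.cnn_config <- function(x, ...) {
  sprintf("cnn_config(lr=%.5g, batch=%d, filters=%d, dropout=%.2f, %s)",
          x$learning_rate, x$batch_size, x$base_filters, x$dropout_rate,
          x$optimizer_kind)
}

#' Ablation: AO-only, HHO-only and the hybrid on the same problem
#'
#' Runs the three optimizers with identical seed, population size and
#' iteration budget (the arms are paired: identical initial populations),
#' attributing performance to each component of the hybrid.
#'
#' @inheritParams ao_hho_optimize
#' @return List with `summary` (data.frame of optimizer, best_objective,
#'   evaluations, converged_early) and `runs` (named list of
#'   `aohho_result`).
#' @export
ablate <- function(fitness_fn, space = hyperparameter_space(),
                   config = hybrid_config(), params = ao_params()) {
  if (is.null(config$seed))
    stop("ablation requires a seed so the three arms share initial populations")
  methods <- c(AO = "ao", HHO = "hho", `AO-HHO` = "aohho")
  runs <- lapply(methods, function(m)
    ao_hho_optimize(fitness_fn, space, config, method = m, params = params))
  list(summary = data.frame(
         optimizer = names(methods),
         best_objective = vapply(runs, `[[`, numeric(1), "best_objective"),
         evaluations = vapply(runs, `[[`, integer(1), "evaluations_used"),
         converged_early = vapply(runs, `[[`, logical(1), "converged_early"),
         row.names = NULL, stringsAsFactors = FALSE),
       runs = runs)
}
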