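#' Aquila Optimizer parameters
#'
#' Constants of the four AO hunting strategies. `s` and `beta` scale the
#' Levy flight, `omega` and `spiral_slope` shape the contour-flight spiral,
#' `alpha` and `delta` damp the low-flight exploitation step, and
#' `exploration_fraction` sets the iteration fraction spent in the two
#' exploration strategies.
#'
#' @param s Levy step scale (> 0).
#' @param beta Levy tail exponent in (0, 2].
#' @param omega spiral angular decay per coordinate.
#' @param alpha,delta exploitation adjustment factors in (0, 1].
#' @param spiral_slope radial growth of the spiral per coordinate.
#' @param r1_max upper bound of the uniform spiral radius draw (lower is 1).
#' @param exploration_fraction fraction of iterations using exploration
#'   strategies X1/X2 before switching to exploitation strategies X3/X4.
#' @param strict_levy if `TRUE`, use the denominator exponent `|v|^beta`
#'   exactly as sometimes printed instead of the Mantegna `|v|^(1/beta)`;
#'   with `beta > 1` the strict form shrinks rather than heavy-tails the
#'   steps, so it is off by default and kept only for comparison.
#' @return Object of class `ao_params`.
#' @export
ao_params <- function(s = 0.01, beta = 1.5, omega = 0.005,
                      alpha = 0.1, delta = 0.1, spiral_slope = 0.00565,
                      r1_max = 20, exploration_fraction = 2 / 3,
                      strict_levy = FALSE) {
  stopifnot(s >= 0, beta > 0, beta <= 2,
            alpha > 0, alpha <= 1, delta > 0, delta <= 1,
            r1_max >= 1, exploration_fraction > 0, exploration_fraction < 1)
  structure(list(s = s, beta = beta, omega = omega, alpha = alpha,
                 delta = delta, spiral_slope = spiral_slope, r1_max = r1_max,
                 exploration_fraction = exploration_fraction,
                 strict_levy = isTRUE(strict_levy)),
            class = "ao_params")
}

#' Population state shared by the AO and HHO drivers
#'
#' Holds the agent positions and fitnesses, the incumbent best, the 1-based
#' iteration counter and the best-so-far trace. The iteration counter is
#' 1-based so that the AO quality function `t^x` is always well defined.
#'
#' @param positions list of numeric vectors (the agents).
#' @param fitnesses numeric vector, one value per agent.
#' @param max_iterations total iteration budget (>= 2).
#' @return Object of class `optimizer_state`.
#' @export
optimizer_state <- function(positions, fitnesses, max_iterations) {
  stopifnot(is.list(positions), length(positions) >= 1L,
            length(fitnesses) == length(positions),
            all(is.finite(fitnesses)), max_iterations >= 2)
  b <- which.min(fitnesses)
  structure(list(positions = positions,
                 fitnesses = as.numeric(fitnesses),
                 best_position = positions[[b]],
                 best_fitness = fitnesses[[b]],
                 iteration = 1L,
                 max_iterations = as.integer(max_iterations),
                 history = numeric(0)),
            class = "optimizer_state")
}

#' Component-wise mean position of the population
#'
#' @param state an [optimizer_state()].
#' @return Numeric vector: the average agent position of the current cycle.
#' @export
mean_position <- function(state) {
  if (length(state$positions) == 0L) stop("empty population")
  Reduce(`+`, state$positions) / length(state$positions)
}

#' Levy-flight scale factor
#'
#' Evaluates the gamma-function expression
#' `Gamma(1+beta) * sin(pi*beta/2) / (Gamma((1+beta)/2) * beta * 2^((beta-1)/2))`.
#' The classic Mantegna recipe raises this bracket to `1/beta`; here the
#' bracket itself is returned and any constant difference in step scale is
#' absorbed by the `s` parameter.
#'
#' @param beta tail exponent in (0, 2].
#' @return The scale sigma.
#' @export
levy_sigma <- function(beta) {
  if (!is.numeric(beta) || beta <= 0 || beta > 2) stop("beta must be in (0, 2]")
  gamma(1 + beta) * sin(pi * beta / 2) /
    (gamma((1 + beta) / 2) * beta * 2 ^ ((beta - 1) / 2))
}

#' Draw a Levy-flight step vector
#'
#' Mantegna's scheme: component-wise `s * u * sigma / |v|^(1/beta)` with
#' `u`, `v` standard normal draws (`u` additionally scaled by
#' [levy_sigma()]). Heavy-tailed: occasional components are far larger than
#' any normal draw, which is what lets the search escape local basins.
#'
#' @param dim vector length (>= 1).
#' @param params an [ao_params()].
#' @return Numeric vector of length `dim`. Uses R's RNG stream.
#' @export
levy_flight <- function(dim, params = ao_params()) {
  stopifnot(dim >= 1)
  sigma <- levy_sigma(params$beta)
  u <- stats::rnorm(dim)
  v <- stats::rnorm(dim)
  expo <- if (params$strict_levy) params$beta else 1 / params$beta
  params$s * u * sigma / abs(v) ^ expo
}

#' Spiral offsets for the contour-flight strategy
#'
#' For coordinate index `D1 = 1..dim`: radius `r = r1 + slope * D1` with a
#' single uniform draw `r1` in `[1, r1_max]`, angle
#' `theta = -omega * D1 + 3*pi/2`, and offsets `x = r*sin(theta)`,
#' `y = r*cos(theta)`.
#'
#' @param dim vector length.
#' @param params an [ao_params()].
#' @return List with numeric vectors `x` and `y` of length `dim`.
#' @export
spiral_offsets <- function(dim, params = ao_params()) {
  stopifnot(dim >= 1)
  r1 <- stats::runif(1, 1, params$r1_max)
  d1 <- seq_len(dim)
  r <- r1 + params$spiral_slope * d1
  theta <- -params$omega * d1 + 3 * pi / 2
  list(x = r * sin(theta), y = r * cos(theta))
}

#' AO schedule coefficients
#'
#' Quality function `QF = t^((2*rand - 1) / (1 - I_max)^2)`, mobility
#' `G1 = 2*rand - 1` (in [-1, 1]) and flight slope `G2 = 2*(1 - t/I_max)`,
#' which decays linearly from 2 to 0.
#'
#' @param t current iteration (1-based).
#' @param I_max iteration budget (> 1).
#' @param rand a uniform draw in [0, 1].
#' @return List with elements `QF`, `G1`, `G2`.
#' @export
ao_coefficients <- function(t, I_max, rand) {
  stopifnot(t >= 1, t <= I_max, rand >= 0, rand <= 1)
  if (I_max == 1) stop("I_max must exceed 1 (QF exponent denominator is zero)")
  list(QF = t ^ ((2 * rand - 1) / (1 - I_max) ^ 2),
       G1 = 2 * rand - 1,
       G2 = 2 * (1 - t / I_max))
}

# ---- raw position-update equations -----------------------------------------
# Exposed with all stochastic inputs as explicit arguments so they can be
# checked term by term against an independent transcription.

#' AO update equations with explicit random inputs
#'
#' The four raw Aquila position updates. `ao_eq_x1` is the high soar with
#' vertical stoop, `ao_eq_x2` the contour flight with short glide attack
#' (spiral plus Levy), `ao_eq_x3` the low-flying strike, and `ao_eq_x4` the
#' walking-and-grabbing attack. All stochastic quantities (uniform draws,
#' Levy vectors, spiral offsets, schedule coefficients, the randomly chosen
#' other agent) enter as arguments; [ao_update()] draws them from R's RNG.
#'
#' @param best incumbent best position.
#' @param mean_pos population mean position.
#' @param t,I_max iteration counter and budget.
#' @param rand,rand1,rand2 uniform draws in [0, 1].
#' @param x_rand another agent's position, chosen uniformly.
#' @param levy a Levy step vector (see [levy_flight()]).
#' @param spiral_x,spiral_y spiral offsets (see [spiral_offsets()]).
#' @param lb,ub search bounds vectors.
#' @param alpha,delta exploitation adjustments.
#' @param x the updating agent's position.
#' @param qf,g1,g2 schedule coefficients (see [ao_coefficients()]).
#' @return Unclipped candidate position.
#' @name ao_equations
NULL

#' @rdname ao_equations
#' @export
ao_eq_x1 <- function(best, mean_pos, t, I_max, rand) {
  best * (1 - t / I_max) + (mean_pos - best * rand)
}

#' @rdname ao_equations
#' @export
ao_eq_x2 <- function(best, levy, x_rand, spiral_x, spiral_y, rand) {
  best * levy + x_rand + (spiral_y - spiral_x) * rand
}

#' @rdname ao_equations
#' @export
ao_eq_x3 <- function(best, mean_pos, lb, ub, alpha, delta, rand1, rand2) {
  (best - mean_pos) * alpha - rand1 + ((ub - lb) * rand2 + lb) * delta
}

#' @rdname ao_equations
#' @export
ao_eq_x4 <- function(best, x, qf, g1, g2, levy, rand1, rand2) {
  qf * best - (g1 * x * rand1) - g2 * levy + rand2 * g1
}

#' Select an AO strategy for the current iteration
#'
#' Exploration strategies (X1, X2) are used for the first
#' `exploration_fraction` of the budget, exploitation strategies (X3, X4)
#' afterwards; within a phase the two strategies are chosen with equal
#' probability.
#'
#' @param t current iteration (1-based).
#' @param I_max iteration budget.
#' @param params an [ao_params()].
#' @return One of `"X1"`, `"X2"`, `"X3"`, `"X4"`.
#' @export
ao_select_mode <- function(t, I_max, params = ao_params()) {
  stopifnot(t >= 1, t <= I_max)
  if (t <= params$exploration_fraction * I_max) {
    if (stats::runif(1) < 0.5) "X1" else "X2"
  } else {
    if (stats::runif(1) < 0.5) "X3" else "X4"
  }
}

#' Propose a new position for one agent with a chosen AO strategy
#'
#' Draws the required random quantities (one scalar draw per scalar `rand`
#' appearance in the equation, shared across components), applies the
#' selected update equation and clips the result into the bounds.
#'
#' @param mode `"X1"`, `"X2"`, `"X3"` or `"X4"`.
#' @param agent_index index of the updating agent in `state$positions`.
#' @param state an [optimizer_state()] with at least 2 agents.
#' @param params an [ao_params()].
#' @param bounds a [search_bounds()].
#' @return Clipped candidate position.
#' @export
ao_update <- function(mode, agent_index, state, params, bounds) {
  if (length(state$positions) < 2L) stop("AO updates need at least 2 agents")
  t <- state$iteration
  I_max <- state$max_iterations
  best <- state$best_position
  x <- state$positions[[agent_index]]
  cand <- switch(mode,
    X1 = ao_eq_x1(best, mean_position(state), t, I_max, stats::runif(1)),
    X2 = {
      others <- setdiff(seq_along(state$positions), agent_index)
      xr <- state$positions[[others[sample.int(length(others), 1L)]]]
      sp <- spiral_offsets(bounds$dimension, params)
      ao_eq_x2(best, levy_flight(bounds$dimension, params), xr,
               sp$x, sp$y, stats::runif(1))
    },
    X3 = ao_eq_x3(best, mean_position(state), bounds$lower, bounds$upper,
                  params$alpha, params$delta, stats::runif(1), stats::runif(1)),
    X4 = {
      co <- ao_coefficients(t, I_max, stats::runif(1))
      ao_eq_x4(best, x, co$QF, co$G1, co$G2,
               levy_flight(bounds$dimension, params),
               stats::runif(1), stats::runif(1))
    },
    stop("unknown AO mode: ", mode))
  clip_to_bounds(cand, bounds)
}

# greedy replacement + best/history bookkeeping shared by AO and HHO
.finish_iteration <- function(state) {
  b <- which.min(state$fitnesses)
  if (state$fitnesses[[b]] < state$best_fitness) {
    state$best_fitness <- state$fitnesses[[b]]
    state$best_position <- state$positions[[b]]
  }
  state$history <- c(state$history, state$best_fitness)
  state$iteration <- state$iteration + 1L
  state
}

.eval_with_context <- function(fitness_fn, x, agent_index) {
  tryCatch(fitness_fn(x), error = function(e)
    stop("fitness evaluation failed for agent ", agent_index, ": ",
         conditionMessage(e), call. = FALSE))
}

#' Run one full AO iteration
#'
#' Each agent proposes a position via [ao_select_mode()] and [ao_update()];
#' the proposal replaces the agent only if its fitness is not worse (greedy
#' retention), so the best-so-far trace is non-increasing.
#'
#' @param state an [optimizer_state()].
#' @param params an [ao_params()].
#' @param bounds a [search_bounds()].
#' @param fitness_fn function mapping a position vector to a finite real.
#' @return The updated state (iteration advanced, history appended).
#' @export
ao_iteration <- function(state, params, bounds, fitness_fn) {
  for (i in seq_along(state$positions)) {
    mode <- ao_select_mode(state$iteration, state$max_iterations, params)
    cand <- ao_update(mode, i, state, params, bounds)
    f <- .eval_with_context(fitness_fn, cand, i)
    if (f <= state$fitnesses[[i]]) {
      state$positions[[i]] <- cand
      state$fitnesses[[i]] <- f
      if (f < state$best_fitness) {
        state$best_fitness <- f
        state$best_position <- cand
      }
    }
  }
  .finish_iteration(state)
}
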