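#' Prey escape energy
#'
#' `E = 2 * E0 * (1 - t/I_max)`: the prey's energy shrinks linearly with the
#' iteration count, moving the hawks from exploration (|E| >= 1) through
#' soft to hard besiege modes.
#'
#' @param E0 initial energy in [-1, 1] (redrawn per agent per iteration).
#' @param t current iteration (1-based).
#' @param I_max iteration budget.
#' @return The scalar energy E.
#' @export
escape_energy <- function(E0, t, I_max) {
  stopifnot(t >= 1, t <= I_max)
  2 * E0 * (1 - t / I_max)
}

#' Prey jump strength
#'
#' `J = 2 * (1 - rand)`, in [0, 2].
#'
#' @param rand uniform draw in [0, 1].
#' @return The jump strength J.
#' @export
jump_strength <- function(rand) {
  stopifnot(rand >= 0, rand <= 1)
  2 * (1 - rand)
}

#' Select the HHO update mode
#'
#' `|E| >= 1` keeps the hawks exploring. Otherwise the escape probability
#' `r` and the energy split the four besiege modes: soft (`r >= 0.5`,
#' `|E| >= 0.5`), hard (`r >= 0.5`, `|E| < 0.5`), soft with progressive
#' rapid dives (`r < 0.5`, `|E| >= 0.5`) and hard with progressive rapid
#' dives (`r < 0.5`, `|E| < 0.5`).
#'
#' @param E escape energy.
#' @param escape_prob the draw `r` in [0, 1].
#' @return One of `"explore"`, `"soft"`, `"hard"`, `"soft_dive"`,
#'   `"hard_dive"`.
#' @export
hho_select_mode <- function(E, escape_prob) {
  stopifnot(escape_prob >= 0, escape_prob <= 1)
  if (abs(E) >= 1) return("explore")
  if (escape_prob >= 0.5) {
    if (abs(E) >= 0.5) "soft" else "hard"
  } else {
    if (abs(E) >= 0.5) "soft_dive" else "hard_dive"
  }
}

#' HHO update equations with explicit random inputs
#'
#' Raw Harris-hawks position updates, with every stochastic input passed in
#' explicitly (see [ao_equations] for the rationale). `|.|` is the
#' component-wise absolute value. `hho_eq_explore_high` /
#' `hho_eq_explore_low` are the two perching strategies; `hho_eq_soft` and
#' `hho_eq_hard` the plain besieges; `hho_eq_dive_y` and `hho_eq_dive_z`
#' the two dive candidates of the progressive-rapid-dive modes, where `S`
#' is a uniform random vector in `[0,1]^D`.
#'
#' @param x_rand a randomly chosen other agent's position.
#' @param x the updating agent's position.
#' @param best incumbent best (prey) position.
#' @param mean_pos population mean position.
#' @param lb,ub bounds vectors.
#' @param r1,r2,r3,r4 uniform draws in [0, 1].
#' @param E escape energy.
#' @param J jump strength.
#' @param y the Y dive candidate.
#' @param S uniform random vector in `[0,1]^D`.
#' @param levy Levy step vector.
#' @return Unclipped candidate position.
#' @name hho_equations
NULL

#' @rdname hho_equations
#' @export
hho_eq_explore_high <- function(x_rand, x, r1, r2) {
  x_rand - r1 * abs(x_rand - 2 * r2 * x)
}

#' @rdname hho_equations
#' @export
hho_eq_explore_low <- function(best, mean_pos, lb, ub, r3, r4) {
  (best - mean_pos) - r3 * (lb + r4 * (ub - lb))
}

#' @rdname hho_equations
#' @export
hho_eq_soft <- function(x, best, E, J) {
  (best - x) - E * abs(J * best - x)
}

#' @rdname hho_equations
#' @export
hho_eq_hard <- function(x, best, E) {
  best - E * abs(best - x)
}

#' @rdname hho_equations
#' @export
hho_eq_dive_y <- function(x, best, E, J) {
  best - E * abs(J * best - x)
}

#' @rdname hho_equations
#' @export
hho_eq_dive_z <- function(y, S, levy) {
  y + S * levy
}

#' HHO exploration move for one agent
#'
#' Draws the perch selector `q` uniformly in [0, 1] (a uniform real, so both
#' branches actually fire) and the branch's own uniform draws, then clips.
#'
#' @param agent_index index of the updating agent.
#' @param state an [optimizer_state()] with at least 2 agents.
#' @param bounds a [search_bounds()].
#' @return Clipped candidate position.
#' @export
hho_explore <- function(agent_index, state, bounds) {
  if (length(state$positions) < 2L) stop("HHO exploration needs at least 2 agents")
  q <- stats::runif(1)
  cand <- if (q >= 0.5) {
    others <- setdiff(seq_along(state$positions), agent_index)
    xr <- state$positions[[others[sample.int(length(others), 1L)]]]
    hho_eq_explore_high(xr, state$positions[[agent_index]],
                        stats::runif(1), stats::runif(1))
  } else {
    hho_eq_explore_low(state$best_position, mean_position(state),
                       bounds$lower, bounds$upper,
                       stats::runif(1), stats::runif(1))
  }
  clip_to_bounds(cand, bounds)
}

#' HHO besiege move for one agent
#'
#' Soft and hard besieges return a single candidate. The progressive
#' rapid-dive modes build the dive pair: `Y` first and, only if `Y` does not
#' improve on the agent, `Z = Y + S * LF(D)`; the better improving candidate
#' is returned together with its fitness, otherwise the agent is kept
#' unchanged (so dive moves never worsen the agent). The hard-dive mode
#' reuses the same Y/Z equations; setting `canonical_hard_dive = TRUE`
#' replaces the agent position with the population mean inside Y, the
#' variant used by the original HHO formulation.
#'
#' @param mode `"soft"`, `"hard"`, `"soft_dive"` or `"hard_dive"`.
#' @param agent_index index of the updating agent.
#' @param state an [optimizer_state()].
#' @param E escape energy for this agent.
#' @param bounds a [search_bounds()].
#' @param fitness_fn fitness function (needed by the dive modes).
#' @param params an [ao_params()]; supplies the shared Levy generator.
#' @param canonical_hard_dive see above; default `FALSE`.
#' @return List with `position` and `fitness` (`NA` when the candidate has
#'   not been evaluated, i.e. for soft/hard besieges).
#' @export
hho_besiege <- function(mode, agent_index, state, E, bounds, fitness_fn,
                        params = ao_params(), canonical_hard_dive = FALSE) {
  x <- state$positions[[agent_index]]
  best <- state$best_position
  if (mode == "soft") {
    J <- jump_strength(stats::runif(1))
    return(list(position = clip_to_bounds(hho_eq_soft(x, best, E, J), bounds),
                fitness = NA_real_))
  }
  if (mode == "hard") {
    return(list(position = clip_to_bounds(hho_eq_hard(x, best, E), bounds),
                fitness = NA_real_))
  }
  if (!mode %in% c("soft_dive", "hard_dive")) stop("unknown HHO mode: ", mode)
  x_ref <- if (mode == "hard_dive" && canonical_hard_dive) mean_position(state) else x
  J <- jump_strength(stats::runif(1))
  fx <- state$fitnesses[[agent_index]]
  y <- clip_to_bounds(hho_eq_dive_y(x_ref, best, E, J), bounds)
  fy <- .eval_with_context(fitness_fn, y, agent_index)
  if (fy < fx) return(list(position = y, fitness = fy))
  S <- stats::runif(bounds$dimension)
  z <- clip_to_bounds(hho_eq_dive_z(y, S, levy_flight(bounds$dimension, params)), bounds)
  fz <- .eval_with_context(fitness_fn, z, agent_index)
  if (fz < fx) return(list(position = z, fitness = fz))
  list(position = x, fitness = fx)
}

#' Run one full HHO iteration
#'
#' Per agent: draw the initial energy `E0` uniformly in [-1, 1] and the
#' escape probability uniformly in [0, 1], compute the escape energy, select
#' a mode, propose, and greedily retain (replace only if not worse). The
#' best-so-far trace is therefore non-increasing.
#'
#' @inheritParams hho_besiege
#' @param state an [optimizer_state()].
#' @return The updated state.
#' @export
hho_iteration <- function(state, bounds, fitness_fn, params = ao_params(),
                          canonical_hard_dive = FALSE) {
  t <- state$iteration
  I_max <- state$max_iterations
  for (i in seq_along(state$positions)) {
    E0 <- stats::runif(1, -1, 1)
    r <- stats::runif(1)
    E <- escape_energy(E0, t, I_max)
    mode <- hho_select_mode(E, r)
    if (mode == "explore") {
      cand <- hho_explore(i, state, bounds)
      f <- .eval_with_context(fitness_fn, cand, i)
    } else {
      res <- hho_besiege(mode, i, state, E, bounds, fitness_fn,
                         params, canonical_hard_dive)
      cand <- res$position
      f <- if (is.na(res$fitness)) .eval_with_context(fitness_fn, cand, i) else res$fitness
    }
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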