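test_that("mean_position averages agent positions component-wise", {
  st <- optimizer_state(list(c(1, 2)), 0.5, 10)
  expect_equal(mean_position(st), c(1, 2))
  st <- optimizer_state(list(c(1, 0), c(-1, 0)), c(1, 1), 10)
  expect_equal(mean_position(st), c(0, 0))
  st <- optimizer_state(list(c(1, 2), c(3, 4), c(5, 6)), c(1, 2, 3), 10)
  expect_equal(mean_position(st), c(3, 4))
})

test_that("levy_sigma matches closed forms and the high-precision gamma oracle", {
  expect_equal(levy_sigma(1.0), 1.0)
  expect_equal(levy_sigma(2.0), 0.0, tolerance = 1e-10)  # sin(pi) = 0
  # frozen values from an arbitrary-precision gamma evaluation (mpmath, 40 digits)
  expect_equal(levy_sigma(0.5), 1.2162802142575202831, tolerance = 1e-10)
  expect_equal(levy_sigma(1.5), 0.58136831701911858184, tolerance = 1e-10)
  expect_error(levy_sigma(0), "beta")
  expect_error(levy_sigma(2.5), "beta")
})

test_that("levy_flight scales with s, is seed-reproducible and heavy-tailed", {
  expect_equal(levy_flight(4, ao_params(s = 0)), rep(0, 4))
  set.seed(5); a <- levy_flight(6)
  set.seed(5); b <- levy_flight(6)
  expect_identical(a, b)
  expect_length(a, 6)
  kurt <- function(x) mean((x - mean(x)) ^ 4) / stats::var(x) ^ 2 - 3
  set.seed(1); lv <- as.vector(replicate(1000, levy_flight(100)))
  set.seed(2); nm <- stats::rnorm(1e5)
  expect_gt(kurt(lv), 100 * max(1, abs(kurt(nm))))
})

test_that("spiral offsets follow the radius/angle recursion and stay bounded", {
  p0 <- ao_params(omega = 0)
  set.seed(3)
  sp <- spiral_offsets(4, p0)
  # theta = 3*pi/2 for every coordinate when omega = 0: x = -r, y = 0
  expect_true(all(sp$x < -1))
  expect_equal(sp$y, rep(0, 4), tolerance = 1e-12)
  # direct substitution: r1 known from the seeded draw
  set.seed(3); r1 <- runif(1, 1, 20)
  expect_equal(sp$x, -(r1 + 0.00565 * (1:4)), tolerance = 1e-12)
  p <- ao_params()
  set.seed(4)
  sp <- spiral_offsets(10, p)
  lim <- p$r1_max + p$spiral_slope * 10
  expect_true(all(abs(sp$x) <= lim) && all(abs(sp$y) <= lim))
})

test_that("schedule coefficients hit their endpoints", {
  co <- ao_coefficients(5, 50, rand = 0.5)
  expect_equal(co$QF, 1)   # zero exponent
  expect_equal(co$G1, 0)
  expect_equal(ao_coefficients(50, 50, 0.2)$G2, 0)
  expect_equal(ao_coefficients(1, 50, 0.9)$QF, 1)  # 1^x = 1
  expect_equal(ao_coefficients(10, 50, 0)$G1, -1)
  expect_equal(ao_coefficients(10, 50, 1)$G1, 1)
  expect_error(ao_coefficients(1, 1, 0.5), "I_max")
  # G2 decays linearly from 2 to 0 in exact steps of 2/I_max
  g2 <- vapply(1:20, function(t) ao_coefficients(t, 20, 0.5)$G2, numeric(1))
  expect_equal(unique(round(-diff(g2), 12)), 2 / 20)
  expect_equal(g2[20], 0)
})

test_that("the four update equations match an independent transcription", {
  best <- c(0.42, -1.13); xm <- c(0.10, -0.22); x <- c(-0.35, 0.77)
  xr <- c(0.91, 0.05); levy <- c(0.013, -0.044)
  spx <- c(-3.2, 1.1); spy <- c(0.7, -2.5)
  lb <- c(-1, -1); ub <- c(2, 2)
  expect_equal(ao_eq_x1(best, xm, t = 7, I_max = 30, rand = 0.613),
               best * (1 - 7 / 30) + (xm - best * 0.613))
  expect_equal(ao_eq_x2(best, levy, xr, spx, spy, rand = 0.271),
               best * levy + xr + (spy - spx) * 0.271)
  expect_equal(ao_eq_x3(best, xm, lb, ub, alpha = 0.1, delta = 0.1,
                        rand1 = 0.44, rand2 = 0.81),
               (best - xm) * 0.1 - 0.44 + ((ub - lb) * 0.81 + lb) * 0.1)
  co <- ao_coefficients(9, 40, 0.37)
  expect_equal(ao_eq_x4(best, x, co$QF, co$G1, co$G2, levy,
                        rand1 = 0.58, rand2 = 0.12),
               co$QF * best - (co$G1 * x * 0.58) - co$G2 * levy + 0.12 * co$G1)
})

test_that("update equations reduce correctly in degenerate cases", {
  best <- c(0.4, -0.6); xm <- c(0.1, 0.2); x <- c(0.3, 0.3)
  # X1 at the last iteration with rand = 0 collapses onto the mean
  expect_equal(ao_eq_x1(best, xm, t = 30, I_max = 30, rand = 0),
               xm)
  # X3 with rand draws 0 keeps only the damped pull plus LB*delta
  expect_equal(ao_eq_x3(best, xm, c(0, 0), c(1, 1), 0.1, 0.1, 0, 0),
               (best - xm) * 0.1 + 0 * 0.1)
  # X4 with rand = 0.5 (QF = 1, G1 = 0) and a zero Levy draw returns the best
  co <- ao_coefficients(10, 50, 0.5)
  expect_equal(ao_eq_x4(best, x, co$QF, co$G1, co$G2, c(0, 0), 0.9, 0.3),
               best)
})

test_that("mode selection respects the exploration/exploitation phases", {
  set.seed(1)
  expect_true(all(replicate(50, ao_select_mode(1, 100)) %in% c("X1", "X2")))
  expect_true(all(replicate(50, ao_select_mode(100, 100)) %in% c("X3", "X4")))
  set.seed(2)
  freq <- mean(replicate(1e4, ao_select_mode(1, 100)) == "X1")
  expect_lt(abs(freq - 0.5), 0.02)
})

test_that("proposals are always clipped into bounds", {
  b <- search_bounds(3, -1, 1)
  set.seed(8)
  pop <- sample_population(6, b)
  st <- optimizer_state(pop, vapply(pop, sphere_fn, numeric(1)), 20)
  for (mode in c("X1", "X2", "X3", "X4"))
    for (rep in 1:20) {
      cand <- ao_update(mode, 1, st, ao_params(), b)
      expect_true(all(cand >= -1 & cand <= 1))
    }
  expect_error(ao_update("X9", 1, st, ao_params(), b), "unknown")
})

test_that("AO iterations keep the population size, elitism and a monotone trace", {
  b <- search_bounds(5, -5.12, 5.12)
  set.seed(42)
  pop <- sample_population(8, b)
  pop[[3]] <- rep(0, 5)  # one agent already at the optimum
  st <- optimizer_state(pop, vapply(pop, sphere_fn, numeric(1)), 30)
  for (t in 1:29) st <- ao_iteration(st, ao_params(), b, sphere_fn)
  expect_length(st$positions, 8)
  expect_equal(st$best_fitness, 0)  # never lost
  expect_true(all(diff(st$history) <= 0))
  expect_true(all(vapply(st$positions, function(x)
    all(x >= -5.12 & x <= 5.12), logical(1))))
})

test_that("fitness failures propagate with agent context", {
  b <- search_bounds(2)
  set.seed(1)
  pop <- sample_population(3, b)
  st <- optimizer_state(pop, c(1, 2, 3), 10)
  expect_error(ao_iteration(st, ao_params(), b,
                            function(x) stop("boom")),
               "agent")
})
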