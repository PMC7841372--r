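test_that("wrap_angle reduces modulo 2*pi into (-pi, pi]", {
  expect_identical(wrap_angle(0), 0)
  expect_equal(wrap_angle(3 * pi / 2), -pi / 2)
  expect_equal(wrap_angle(-pi), pi)
  expect_equal(wrap_angle(pi), pi)
  # congruence property on a grid of offsets
  th <- seq(-0.9 * pi, 0.9 * pi, length.out = 7)
  for (k in -3:3) {
    expect_equal(wrap_angle(th + 2 * pi * k), th, tolerance = 1e-12)
  }
  expect_error(wrap_angle(Inf), "finite")
  expect_error(wrap_angle(NA_real_), "finite")
})

test_that("heading_self adds skill-attenuated noise and wraps", {
  expect_equal(heading_self(0.3, 0, 10), 0.3)
  expect_equal(heading_self(0, 0.5, 10), 0.05)
  expect_equal(heading_self(pi - 0.01, 0.5, 1), -(pi - 0.49))
  expect_error(heading_self(0, 0, 0), "positive")
  expect_error(heading_self(0, 0, -2), "positive")
})

test_that("periodic_distance uses the minimum image", {
  expect_identical(periodic_distance(c(1, 1), c(1, 1), 5), 0)
  expect_equal(periodic_distance(c(0.1, 0), c(4.9, 0), 5), 0.2)
  expect_equal(periodic_distance(c(0, 0), c(2.5, 2.5), 5), 2.5 * sqrt(2))
  # oracle: minimum over the 9 image translates
  set.seed(11)
  for (k in 1:25) {
    a <- runif(2, 0, 5); b <- runif(2, 0, 5)
    expect_equal(periodic_distance(a, b, 5),
                 brute_periodic_distance(a, b, 5), tolerance = 1e-12)
  }
  # never exceeds L / sqrt(2)
  set.seed(12)
  d <- replicate(100, periodic_distance(runif(2, 0, 5), runif(2, 0, 5), 5))
  expect_true(all(d <= 5 / sqrt(2) + 1e-12))
})

test_that("circular_mean_in_radius averages neighbours on the circle", {
  ag <- data.frame(x = c(1, 1.2), y = c(1, 1), theta = c(0, pi / 2))
  expect_equal(circular_mean_in_radius(ag, 1, r = 1, L = 5), pi / 4)
  expect_equal(circular_mean_in_radius(ag, 2, r = 1, L = 5), pi / 4)

  # near the branch cut the vector mean lands on pi, not 0
  ag2 <- data.frame(x = c(1, 1.2), y = c(1, 1),
                    theta = c(pi - 0.1, -pi + 0.1))
  direct <- atan2(sum(sin(ag2$theta)) / 2, sum(cos(ag2$theta)) / 2)
  expect_equal(circular_mean_in_radius(ag2, 1, r = 1, L = 5), pi)
  expect_equal(circular_mean_in_radius(ag2, 1, r = 1, L = 5), direct)

  # out of range (even across the boundary): own heading unchanged
  ag3 <- data.frame(x = c(0.1, 2.5), y = c(0, 0), theta = c(0.7, -1))
  expect_identical(circular_mean_in_radius(ag3, 1, r = 1, L = 5), 0.7)
  # ... but wrap-around neighbours do count
  ag4 <- data.frame(x = c(0.1, 4.9), y = c(0, 0), theta = c(0, pi / 2))
  expect_equal(circular_mean_in_radius(ag4, 1, r = 1, L = 5), pi / 4)
})

test_that("heading_update mixes the two terms as a literal weighted sum", {
  expect_equal(heading_update(0.4, 2.2, 0, 0, 10, alpha = 1, beta = 0), 0.4)
  expect_equal(heading_update(0, pi / 2, 0, 0, 10, alpha = 0.5, beta = 0.5),
               pi / 4)
  # hand-computed affine form: 0.95 * 0.205 + 0.05 * 0.595
  expect_equal(heading_update(0.2, 0.6, xi2 = 0.5, xi3 = -0.5, p = 100,
                              alpha = 0.95, beta = 0.05), 0.22450)
  expect_error(heading_update(0, 0, 0, 0, 10, alpha = 0.6, beta = 0.5),
               "alpha")
  expect_error(heading_update(0, 0, 0, 0, -1, alpha = 1, beta = 0),
               "positive")
})

test_that("circular mixing agrees with scalar mixing away from the cut", {
  sc <- heading_update(0.2, 0.6, 0, 0, 10, 0.5, 0.5, mix = "scalar")
  ci <- heading_update(0.2, 0.6, 0, 0, 10, 0.5, 0.5, mix = "circular")
  expect_equal(sc, 0.4)
  expect_equal(ci, 0.4, tolerance = 1e-12)
  # and differs across it, where the scalar sum averages through zero
  sc2 <- heading_update(pi - 0.1, -pi + 0.1, 0, 0, 10, 0.5, 0.5, "scalar")
  ci2 <- heading_update(pi - 0.1, -pi + 0.1, 0, 0, 10, 0.5, 0.5, "circular")
  expect_equal(sc2, 0)
  expect_equal(abs(ci2), pi)
})

test_that("position_update advances at speed kappa and wraps the box", {
  expect_equal(position_update(c(0, 0), 0, c(0, 0), 10, 0.05, 5), c(0.05, 0))
  expect_equal(position_update(c(4.99, 2), 0, c(0, 0), 10, 0.05, 5),
               c(0.04, 2))
  expect_equal(position_update(c(1, 1), pi / 2, c(0.5, -0.5), 10, 0.05, 5),
               c(1.05, 1.0), tolerance = 1e-12)
  expect_error(position_update(c(0, 0), 0, c(0, 0), 0, 0.05, 5), "positive")
})

test_that("noise-free limits: straight-line motion and alignment fixed point", {
  # single agent, couplings off: heading constant, displacement exactly kappa
  tr <- noise_free_run(pk_config(n_steps = 30), x = 1, y = 2, theta = 0.3)
  expect_equal(unique(tr$theta), 0.3)
  step_len <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  expect_equal(step_len, rep(0.05, 30), tolerance = 1e-12)

  # two agents inside r, headings {0, pi/2}: both next headings pi/4
  cfg <- pk_config(n_agents = 2, xi = 0, p = 10)
  nxt <- step_agents(data.frame(x = c(1, 1.3), y = c(1, 1),
                                theta = c(0, pi / 2), p = c(10, 10)), cfg)
  expect_equal(nxt$theta, c(pi / 4, pi / 4))
})

test_that("compiled stepper reproduces the scalar reference draw-for-draw", {
  configs <- list(
    pk_config(n_steps = 120),                                   # free motion
    pk_config(n_steps = 120, alpha = 0.5, beta = 0.5,
              env_enabled = TRUE),                              # gradient
    tiny_config(n_steps = 120),                                 # social
    pk_config(n_agents = 2, n_steps = 120, alpha = 0.95, beta = 0.05,
              env_enabled = TRUE, p = c(2, 80)),                # joint
    pk_config(n_agents = 2, n_steps = 120, alpha = 0.5, beta = 0.5,
              env_enabled = TRUE, p = 30, mix = "circular")     # circular mix
  )
  for (cfg in configs) {
    a <- skillflock:::sim_run(cfg, seed = 91, engine = "compiled")
    b <- skillflock:::sim_run(cfg, seed = 91, engine = "reference")
    expect_equal(a$x, b$x, tolerance = 1e-9)
    expect_equal(a$y, b$y, tolerance = 1e-9)
    expect_equal(a$theta, b$theta, tolerance = 1e-9)
  }
})

test_that("trajectories stay inside the box and the angle interval", {
  for (cfg in list(pk_config(n_steps = 400, p = 1, xi = 5),
                   tiny_config(n_steps = 400, xi = 2.5,
                               alpha = 0.5, beta = 0.5, env_enabled = TRUE))) {
    tr <- simulate_agents(cfg, seed = 17)
    expect_true(all(tr$x >= 0 & tr$x < cfg$L))
    expect_true(all(tr$y >= 0 & tr$y < cfg$L))
    expect_true(all(tr$theta > -pi & tr$theta <= pi))
  }
})

test_that("identical seeds give bitwise-identical trajectories", {
  cfg <- tiny_config(alpha = 0.5, beta = 0.5, env_enabled = TRUE)
  t1 <- simulate_agents(cfg, seed = 5)
  t2 <- simulate_agents(cfg, seed = 5)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$theta, t2$theta)
  t3 <- simulate_agents(cfg, seed = 6)
  expect_false(identical(t1$x, t3$x))
})

test_that("n_steps = 0 yields only the initial snapshot", {
  tr <- simulate_agents(pk_config(n_steps = 0), seed = 2)
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$step, 0L)
})

test_that("heading increments follow the uniform noise law", {
  # sd of uniform(-xi, xi)/p increments is xi / (p * sqrt(3))
  cfg <- pk_config(n_steps = 12000, p = 100, xi = 0.5)
  tr <- simulate_agents(cfg, seed = 23)
  expect_equal(heading_increment_sd(tr), 0.5 / (100 * sqrt(3)),
               tolerance = 0.05)
})

test_that("heading-increment spread strictly decreases with skill", {
  sds <- vapply(c(1, 5, 10, 20, 50, 100), function(p) {
    tr <- simulate_agents(pk_config(n_steps = 3000, p = p, xi = 0.5),
                          seed = 31)
    heading_increment_sd(tr)
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})
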