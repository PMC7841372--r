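test_that("run_ensemble is reproducible and reduces to a single run", {
  cfg <- pk_config(n_steps = 150, alpha = 0.5, beta = 0.5, env_enabled = TRUE,
                   p = 50)
  e1 <- run_ensemble(cfg, 5, seed = 4)
  e2 <- run_ensemble(cfg, 5, seed = 4)
  expect_identical(tidy(e1), tidy(e2))
  expect_identical(glance(e1), glance(e2))

  # n_experiments = 1 is just one simulate() plus its statistics
  e3 <- run_ensemble(cfg, 1, seed = 9)
  tr <- simulate_agents(cfg, seed = tidy(e3)$seed[1])
  expect_equal(tidy(e3)$tau, arrival_times(tr)$tau)
})

test_that("ensemble summaries match a run-by-run scalar recomputation", {
  cfg <- pk_config(n_agents = 2, n_steps = 300, alpha = 0.95, beta = 0.05,
                   env_enabled = TRUE, p = 50)
  ens <- run_ensemble(cfg, 8, seed = 13)
  per <- tidy(ens)
  redone <- vapply(seq_len(nrow(per)), function(k) {
    tr <- simulate_agents(cfg, seed = per$seed[k])
    at <- arrival_times(tr)$tau
    if (anyNA(at)) NA_real_ else mean(at)
  }, numeric(1))
  expect_identical(per$tau, redone)
  expect_identical(glance(ens)$s, mean(!is.na(redone)))
})

test_that("replicate and cell seed streams are disjoint", {
  cfg <- pk_config(n_steps = 10)
  ens <- run_ensemble(cfg, 20, seed = 1)
  expect_identical(anyDuplicated(tidy(ens)$seed), 0L)

  sw <- experiment_single_agent_env(p_list = c(1, 10), cfg = pk_config(n_steps = 10),
                                    n_experiments = 2, seed = 1)
  expect_identical(anyDuplicated(sw$cell_seed), 0L)
  # different cells produce genuinely different draw histories
  e_a <- run_ensemble(cfg, 3, seed = sw$cell_seed[1])
  e_b <- run_ensemble(cfg, 3, seed = sw$cell_seed[2])
  expect_false(any(tidy(e_a)$seed %in% tidy(e_b)$seed))
})

test_that("free-motion sweep recovers the uniform increment law", {
  sw <- experiment_self(p_list = c(1, 100), xi_list = c(0.5, 5),
                        n_experiments = 30, seed = 2)
  expect_identical(nrow(sw), 4L)
  expect_true(all(sw$n_increments >= 7000))
  # the uniform law holds where kicks are below the wrapping scale (xi/p < pi)
  unwrapped <- sw$xi / sw$p < pi
  expect_equal(sw$increment_sd[unwrapped], sw$increment_sd_theory[unwrapped],
               tolerance = 0.05)
  # wrapped kicks can only shrink the spread
  expect_true(all(sw$increment_sd <= sw$increment_sd_theory * 1.05))
  # linear scaling in xi at fixed p: xi = 5 is 10x the xi = 0.5 spread
  r <- sw$increment_sd[sw$p == 100 & sw$xi == 5] /
    sw$increment_sd[sw$p == 100 & sw$xi == 0.5]
  expect_equal(r, 10, tolerance = 0.1)
  expect_s3_class(sw$trajectory[[1]], "pk_trajectory")
})

test_that("gradient search improves with skill and tau_norm spans [0, 1]", {
  sw <- experiment_single_agent_env(p_list = c(1, 10, 100),
                                    cfg = pk_config(n_steps = 1200),
                                    n_experiments = 60, seed = 3)
  expect_identical(names(sw)[1:5], c("p1", "p2", "xi", "alpha", "beta"))
  # success never degrades with skill, and skilled agents arrive much faster
  expect_true(all(diff(sw$s) > -0.05))
  expect_gte(sw$s[sw$p1 == 100], 0.95)
  expect_lt(sw$mean_tau[sw$p1 == 100], sw$mean_tau[sw$p1 == 1] / 2)
  fin <- sw$tau_norm[is.finite(sw$tau_norm)]
  expect_equal(range(fin), c(0, 1))
})

test_that("joint-task sweep covers the weight pairs deterministically", {
  sw <- experiment_joint_task(p_list = 50,
                              alpha_beta = list(c(1, 0), c(0.5, 0.5)),
                              cfg = pk_config(n_agents = 2, n_steps = 400),
                              n_experiments = 10, seed = 6)
  expect_identical(nrow(sw), 2L)
  expect_setequal(sw$alpha, c(1, 0.5))
  sw2 <- experiment_joint_task(p_list = 50,
                               alpha_beta = list(c(1, 0), c(0.5, 0.5)),
                               cfg = pk_config(n_agents = 2, n_steps = 400),
                               n_experiments = 10, seed = 6)
  expect_identical(tibble::as_tibble(sw), tibble::as_tibble(sw2))
})

test_that("noise-free gradient following respects the kinematic floor", {
  # a deterministic gradient follower cannot beat (d0 - eps) / kappa steps
  cfg <- pk_config(n_steps = 600, alpha = 0.5, beta = 0.5, env_enabled = TRUE,
                   arrival_epsilon = 0.1)
  for (d0 in c(0.8, 1.6, 2.2)) {
    tr <- noise_free_run(cfg, x = 2.5 - d0, y = 2.5, theta = pi / 3)
    tau <- first_arrival(tr)
    expect_false(is.na(tau))
    expect_gte(tau, (d0 - cfg$arrival_epsilon) / cfg$kappa)
  }
})

test_that("min_coordinating_p picks the smallest coordinated diagonal cell", {
  sw <- tibble::tibble(p1 = c(1, 5, 10, 20), p2 = c(1, 5, 10, 20),
                       coordinated = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(min_coordinating_p(sw), 10)
  sw$coordinated <- FALSE
  expect_true(is.na(min_coordinating_p(sw)))
})
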