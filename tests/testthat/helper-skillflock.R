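# Shared fixtures: everything is generated in code at test time.

# A tiny two-agent config for fast dynamical tests.
tiny_config <- function(...) {
  args <- utils::modifyList(list(n_agents = 2, n_steps = 50, p = c(5, 50)),
                            list(...))
  do.call(pk_config, args)
}

# Build a pk_trajectory by hand from snapshot matrices (step-major tibble),
# for metric tests that need exactly known paths.
manual_trajectory <- function(X, Y, TH, cfg) {
  skillflock:::as_trajectory(list(x = X, y = Y, theta = TH),
                             validate_config(cfg))
}

# A noise-free run from a fixed initial state.
noise_free_run <- function(cfg, x, y, theta, p = 100) {
  cfg$xi <- 0
  simulate_agents(validate_config(cfg), seed = 1,
                  init = data.frame(x = x, y = y, theta = theta, p = p))
}

# Brute-force periodic distance: minimum over the 9 image translates.
brute_periodic_distance <- function(a, b, L) {
  best <- Inf
  for (sx in c(-L, 0, L)) for (sy in c(-L, 0, L)) {
    best <- min(best, sqrt(sum((a - (b + c(sx, sy)))^2)))
  }
  best
}
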