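#' Run a seeded ensemble of replicate simulations
#'
#' Performs `n_experiments` independent runs of [simulate_agents()] under one
#' configuration and reduces them with the [ensemble_stats()] observables.
#' Replicate seeds are drawn once from the master-seeded RNG, so the whole
#' ensemble -- every replicate trajectory and every summary -- is exactly
#' reproducible from `(cfg, seed)`, and ensembles with different master seeds
#' use disjoint replicate seeds with overwhelming probability.
#'
#' @param cfg A [pk_config()].
#' @param n_experiments Number of replicates (>= 1).
#' @param seed Master seed for the ensemble.
#' @param engine Simulation engine, as in [simulate_agents()].
#' @param arrival Task convention for run success and first-arrival time, as
#'   in [ensemble_stats()]: `"each"` (default) or `"simultaneous"`.
#' @return A `pk_ensemble`; see [tidy()]/[glance()] methods in
#'   [ensemble_stats()].
#' @examples
#' ens <- run_ensemble(pk_config(n_steps = 200, p = 100), 10, seed = 1)
#' glance(ens)
#' @export
run_ensemble <- function(cfg, n_experiments, seed,
                         engine = c("compiled", "reference"),
                         arrival = c("each", "simultaneous")) {
  engine <- match.arg(engine)
  arrival <- match.arg(arrival)
  cfg <- validate_config(cfg)
  stopifnot(n_experiments >= 1)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, n_experiments)
  per_run <- purrr::map_dfr(seq_len(n_experiments), function(k) {
    mats <- sim_run(cfg, seed = run_seeds[k], engine = engine)
    arr <- run_arrival(mats$x, mats$y, cfg$L, cfg$arrival_epsilon, arrival)
    tibble::tibble(
      run = k, seed = run_seeds[k],
      success = arr$success, tau = arr$tau,
      va_final = final_window_va(mats$theta, cfg$window)
    )
  })
  new_ensemble(per_run, cfg, cfg$arrival_epsilon, cfg$coordination_threshold,
               cfg$window, arrival = arrival, master_seed = seed)
}

# Run one ensemble per row of a cell grid and bind the glances into a tidy
# sweep table. `grid` may carry p1, p2, xi, alpha, beta columns; anything
# absent is filled from `cfg`. Cell seeds are drawn once from the master seed.
run_sweep <- function(grid, cfg, n_experiments, seed,
                      norm_by = character(), arrival = "each") {
  cfg <- validate_config(cfg)
  stopifnot(nrow(grid) >= 1)
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max, nrow(grid))
  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(k) {
    cell <- grid[k, , drop = FALSE]
    over <- as.list(cell)
    cfg_k <- cfg
    if (!is.null(over$xi)) cfg_k$xi <- over$xi
    if (!is.null(over$alpha)) cfg_k$alpha <- over$alpha
    if (!is.null(over$beta)) cfg_k$beta <- over$beta
    p1 <- if (!is.null(over$p1)) over$p1 else skill_vector(cfg_k)[1]
    p2 <- if (cfg_k$n_agents >= 2) {
      if (!is.null(over$p2)) over$p2 else rev(skill_vector(cfg_k))[1]
    } else {
      NA_real_
    }
    cfg_k$p <- if (cfg_k$n_agents == 1) p1 else c(p1, rep(p2, cfg_k$n_agents - 1L))
    cfg_k <- validate_config(cfg_k)
    g <- glance(run_ensemble(cfg_k, n_experiments, seed = cell_seeds[k],
                             arrival = arrival))
    tibble::tibble(
      p1 = p1, p2 = p2, xi = cfg_k$xi, alpha = cfg_k$alpha, beta = cfg_k$beta,
      cell_seed = cell_seeds[k]
    ) |>
      dplyr::bind_cols(g)
  })
  rows <- dplyr::group_by(rows, dplyr::across(dplyr::all_of(norm_by)))
  rows <- dplyr::mutate(rows, tau_norm = safe_tau_norm(.data$mean_tau))
  rows <- dplyr::ungroup(rows)
  rows <- dplyr::relocate(rows, "tau_norm", .after = "mean_tau")
  rows <- dplyr::arrange(rows,
                         dplyr::across(dplyr::any_of(c("alpha", "xi", "p1", "p2"))))
  structure(rows, master_seed = seed, base_config = cfg,
            class = c("pk_sweep", class(rows)))
}

# Min-max normalize where well-defined, NA otherwise (the strict contract
# lives in tau_normalize()).
safe_tau_norm <- function(taus) {
  fin <- taus[is.finite(taus)]
  if (length(unique(fin)) < 2) return(rep(NA_real_, length(taus)))
  tau_normalize(taus)
}

#' Free-motion skill sweep
#'
#' The isolated-agent experiment: a single agent with no environmental or
#' social coupling, so its heading performs a bounded random walk with
#' i.i.d. uniform increments on `[-xi/p, xi/p]`. For every `(p, xi)` cell the
#' sweep keeps one full trajectory (for plotting) and estimates the
#' heading-increment standard deviation from an ensemble of runs, next to its
#' closed form `xi / (p * sqrt(3))`. Skilled agents (large `p`) hold their
#' heading and move near-ballistically; unskilled ones wander erratically.
#'
#' @param p_list Skill values to sweep.
#' @param xi_list Noise half-widths to sweep.
#' @param cfg Base configuration; agent count and couplings are forced to the
#'   single-agent free case. The default horizon is 250 steps.
#' @param n_experiments Replicates per cell for the increment statistics.
#' @param seed Master seed.
#' @return Tibble with columns `p`, `xi`, `n_increments`, `increment_sd`,
#'   `increment_sd_theory`, and a `trajectory` list-column.
#' @export
experiment_self <- function(p_list = c(1, 10, 100), xi_list = 0.5,
                            cfg = pk_config(n_steps = 250),
                            n_experiments = 40, seed = 1) {
  cfg$n_agents <- 1L
  cfg$env_enabled <- FALSE
  cfg$social_enabled <- FALSE
  cfg$alpha <- 1; cfg$beta <- 0
  cfg <- validate_config(cfg)
  grid <- tidyr::expand_grid(xi = xi_list, p = p_list)
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max, nrow(grid))
  purrr::map_dfr(seq_len(nrow(grid)), function(k) {
    cfg_k <- cfg
    cfg_k$p <- grid$p[k]
    cfg_k$xi <- grid$xi[k]
    set.seed(cell_seeds[k])
    run_seeds <- sample.int(.Machine$integer.max, n_experiments)
    incs <- unlist(lapply(run_seeds, function(s) {
      th <- sim_run(cfg_k, seed = s)$theta[, 1]
      wrap_angle(diff(th))
    }))
    tibble::tibble(
      p = grid$p[k], xi = grid$xi[k],
      n_increments = length(incs),
      increment_sd = sd(incs),
      increment_sd_theory = grid$xi[k] / (grid$p[k] * sqrt(3)),
      trajectory = list(simulate_agents(cfg_k, seed = run_seeds[1]))
    )
  })
}

#' Single-agent gradient-search sweep
#'
#' The agent-environment experiment: one agent couples its heading to the
#' concentration gradient with equal weights (`alpha = beta = 0.5`) and tries
#' to reach the field centre. Sweeps skill `p` and reports success rate,
#' mean first-arrival time, and its min-max normalization across the sweep.
#'
#' @param p_list Skill values to sweep.
#' @param cfg Base configuration; forced to one agent with the environmental
#'   coupling on and the social coupling off.
#' @param n_experiments Replicates per cell.
#' @param seed Master seed.
#' @param arrival Task convention for run success, as in [ensemble_stats()].
#' @return A `pk_sweep` tibble (one row per `p`).
#' @export
experiment_single_agent_env <- function(p_list = c(1, 5, 10, 20, 30, 40, 50, 100),
                                        cfg = pk_config(),
                                        n_experiments = 500, seed = 1,
                                        arrival = "each") {
  cfg$n_agents <- 1L
  cfg$social_enabled <- FALSE
  cfg$env_enabled <- TRUE
  cfg$alpha <- 0.5; cfg$beta <- 0.5
  cfg <- validate_config(cfg)
  run_sweep(tibble::tibble(p1 = p_list), cfg, n_experiments, seed,
            arrival = arrival)
}

#' Two-agent coordination sweep
#'
#' The social-only experiment: two agents with the Vicsek alignment rule and
#' no environmental coupling. Sweeps noise `xi` and skill, either along the
#' diagonal `p1 = p2` (curves of the order parameter against noise) or over
#' the full `(p1, p2)` grid per `xi` (heatmaps).
#'
#' @param p_list Skill values.
#' @param xi_list Noise half-widths.
#' @param cfg Base configuration; forced to two agents, social on, env off.
#' @param n_experiments Replicates per cell.
#' @param seed Master seed.
#' @param p_grid If `TRUE`, cross `p_list` with itself into a `(p1, p2)`
#'   grid; otherwise set `p1 = p2 = p`.
#' @return A `pk_sweep` tibble.
#' @export
experiment_two_agent_coordination <- function(p_list = c(1, 5, 10, 20, 30, 40, 50, 100),
                                              xi_list = c(0.1, 0.5, 1.0, 2.5, 5.0),
                                              cfg = pk_config(n_agents = 2),
                                              n_experiments = 500, seed = 1,
                                              p_grid = FALSE) {
  cfg$n_agents <- 2L
  cfg$social_enabled <- TRUE
  cfg$env_enabled <- FALSE
  cfg$alpha <- 1; cfg$beta <- 0
  cfg <- validate_config(cfg)
  grid <- if (p_grid) {
    tidyr::expand_grid(xi = xi_list, p1 = p_list, p2 = p_list)
  } else {
    tidyr::expand_grid(xi = xi_list, p1 = p_list) |>
      dplyr::mutate(p2 = .data$p1)
  }
  run_sweep(grid, cfg, n_experiments, seed, norm_by = "xi")
}

#' Joint search-and-coordination sweep
#'
#' The full two-agent task: reach the concentration centre together while
#' aligning headings. Both couplings are active; the sweep crosses skill with
#' the `(alpha, beta)` weightings of self/social versus environmental
#' information and reports success rate, mean first-arrival time (normalized
#' within each weighting), mean final-window order parameter, and the
#' coordination judgment.
#'
#' @param p_list Skill values (applied as `p1 = p2 = p` unless `p_grid`).
#' @param alpha_beta List of `c(alpha, beta)` weight pairs.
#' @param cfg Base configuration; forced to two agents with both couplings on.
#' @param n_experiments Replicates per cell.
#' @param seed Master seed.
#' @param p_grid If `TRUE`, cross `p_list` with itself into a `(p1, p2)` grid
#'   for each weight pair.
#' @param arrival Task convention for run success, as in [ensemble_stats()].
#' @return A `pk_sweep` tibble.
#' @examples
#' \donttest{
#' sw <- experiment_joint_task(p_list = c(10, 50), n_experiments = 20, seed = 1)
#' sw
#' }
#' @export
experiment_joint_task <- function(p_list = c(1, 5, 10, 20, 30, 40, 50, 100),
                                  alpha_beta = list(c(1, 0), c(0.95, 0.05),
                                                    c(0.5, 0.5), c(0.05, 0.95)),
                                  cfg = pk_config(n_agents = 2),
                                  n_experiments = 500, seed = 1,
                                  p_grid = FALSE, arrival = "each") {
  cfg$n_agents <- 2L
  cfg$social_enabled <- TRUE
  cfg$env_enabled <- TRUE
  cfg <- validate_config(cfg)
  ab <- tibble::tibble(
    alpha = vapply(alpha_beta, `[`, numeric(1), 1),
    beta = vapply(alpha_beta, `[`, numeric(1), 2)
  )
  pg <- if (p_grid) {
    tidyr::expand_grid(p1 = p_list, p2 = p_list)
  } else {
    tibble::tibble(p1 = p_list, p2 = p_list)
  }
  grid <- tidyr::expand_grid(ab, pg)
  run_sweep(grid, cfg, n_experiments, seed, norm_by = c("alpha", "beta"),
            arrival = arrival)
}

#' Smallest skill achieving coordination in a sweep
#'
#' Scans a sweep restricted to `p1 = p2` and returns the smallest skill value
#' whose ensemble is judged coordinated (mean final-window order parameter at
#' or above the threshold recorded in the sweep).
#'
#' @param sweep A `pk_sweep` from a coordination experiment.
#' @return The smallest coordinating `p`, or `NA` if none coordinates.
#' @export
min_coordinating_p <- function(sweep) {
  diag_rows <- dplyr::filter(sweep, is.na(.data$p2) | .data$p1 == .data$p2,
                             .data$coordinated)
  if (nrow(diag_rows) == 0) return(NA_real_)
  min(diag_rows$p1)
}
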