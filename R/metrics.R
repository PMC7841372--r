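#' Velocity order parameter
#'
#' The Vicsek order parameter of a set of headings:
#' \deqn{v_a = \frac{1}{n\kappa}\left\| \sum_i \kappa(\cos\theta_i, \sin\theta_i) \right\|,}
#' which is 1 for perfectly aligned headings and 0 for exactly cancelling
#' ones. The step length `kappa` cancels algebraically but is kept in the
#' expression for fidelity to the model's velocity vectors.
#'
#' @param headings Non-empty numeric vector of headings (radians).
#' @param kappa Step length (any positive value; does not affect the result).
#' @return Scalar in `[0, 1]`.
#' @examples
#' order_parameter(c(0.3, 0.3)) # 1
#' order_parameter(c(0, pi))    # 0
#' order_parameter(c(0, pi / 2)) # sqrt(2) / 2
#' @export
order_parameter <- function(headings, kappa = 0.05) {
  if (length(headings) == 0) stop("`headings` must be non-empty", call. = FALSE)
  n <- length(headings)
  vx <- sum(kappa * cos(headings))
  vy <- sum(kappa * sin(headings))
  sqrt(vx^2 + vy^2) / (n * kappa)
}

#' Per-step order parameter of a trajectory
#'
#' @param traj A `pk_trajectory`.
#' @return Tibble with columns `step`, `va`.
#' @export
order_parameter_series <- function(traj) {
  cfg <- attr(traj, "config")
  kappa <- if (is.null(cfg)) 0.05 else cfg$kappa
  out <- dplyr::group_by(traj, .data$step)
  out <- dplyr::summarise(out, va = order_parameter(.data$theta, kappa),
                          .groups = "drop")
  out
}

# Fast path on a snapshot heading matrix ((n_steps + 1) x n_agents).
va_series_matrix <- function(theta_mat) {
  n <- ncol(theta_mat)
  vx <- rowSums(cos(theta_mat))
  vy <- rowSums(sin(theta_mat))
  sqrt(vx^2 + vy^2) / n
}

# Mean v_a over the final `window` fraction of a run.
final_window_va <- function(theta_mat, window) {
  k <- max(1L, as.integer(ceiling(window * nrow(theta_mat))))
  mean(tail(va_series_matrix(theta_mat), k))
}

# First step at which every agent is within eps of the centre, on snapshot
# matrices; NA_integer_ if never.
first_arrival_matrix <- function(X, Y, L, eps) {
  c0 <- L / 2
  inside <- (X - c0)^2 + (Y - c0)^2 <= eps^2 * (1 + 1e-9)
  all_in <- if (ncol(X) == 1L) inside[, 1] else rowSums(inside) == ncol(X)
  hit <- which(all_in)
  if (length(hit) == 0) NA_integer_ else as.integer(hit[1] - 1L)
}

# Per-agent first entry into the eps-disk, on snapshot matrices.
arrival_times_matrix <- function(X, Y, L, eps) {
  c0 <- L / 2
  inside <- (X - c0)^2 + (Y - c0)^2 <= eps^2 * (1 + 1e-9)
  vapply(seq_len(ncol(X)), function(j) {
    hit <- which(inside[, j])
    if (length(hit) == 0) NA_real_ else hit[1] - 1
  }, numeric(1))
}

# Run-level success flag and first-arrival time under a task convention.
# "each": the run succeeds when every agent enters the disk at some time;
#   tau is the mean of the agents' individual first arrivals.
# "simultaneous": the run succeeds when all agents are inside at one step;
#   tau is that step.
run_arrival <- function(X, Y, L, eps, arrival = c("each", "simultaneous")) {
  arrival <- match.arg(arrival)
  if (arrival == "simultaneous") {
    tau <- first_arrival_matrix(X, Y, L, eps)
    return(list(success = !is.na(tau), tau = as.numeric(tau)))
  }
  times <- arrival_times_matrix(X, Y, L, eps)
  if (anyNA(times)) list(success = FALSE, tau = NA_real_)
  else list(success = TRUE, tau = mean(times))
}

#' First-arrival time at the field centre
#'
#' The smallest step `t` (0-based, counting the initial snapshot as step 0)
#' at which every agent lies within `epsilon` of the field centre
#' `(L/2, L/2)` in plain (non-periodic) Euclidean distance -- the centre is
#' interior, so periodicity is irrelevant. For a single agent this is that
#' agent's arrival; for two agents both must be inside the tolerance disk
#' simultaneously.
#'
#' @param traj A `pk_trajectory`.
#' @param epsilon Arrival tolerance (> 0); defaults to the trajectory
#'   configuration's `arrival_epsilon`.
#' @return Integer step of first arrival, or `NA` if the run never arrives.
#' @export
first_arrival <- function(traj, epsilon = NULL) {
  cfg <- attr(traj, "config")
  if (is.null(epsilon)) {
    if (is.null(cfg)) stop("supply `epsilon` for bare trajectories", call. = FALSE)
    epsilon <- cfg$arrival_epsilon
  }
  stopifnot(epsilon > 0)
  L <- if (is.null(cfg)) stop("trajectory lacks a config", call. = FALSE) else cfg$L
  wide_x <- tidyr::pivot_wider(traj[c("step", "agent_id", "x")],
                               names_from = "agent_id", values_from = "x")
  wide_y <- tidyr::pivot_wider(traj[c("step", "agent_id", "y")],
                               names_from = "agent_id", values_from = "y")
  X <- as.matrix(wide_x[-1])
  Y <- as.matrix(wide_y[-1])
  first_arrival_matrix(X, Y, L, epsilon)
}

#' Per-agent first-arrival times
#'
#' Each agent's own first entry into the `epsilon`-disk around the field
#' centre, regardless of where the other agents are at that moment.
#'
#' The disk-boundary comparison carries a relative slack of `1e-9` so that
#' exact-kinematics cases (an agent grazing the boundary after many equal
#' steps) are not missed through accumulated round-off.
#'
#' @inheritParams first_arrival
#' @return Tibble with columns `agent_id`, `tau` (`NA` when that agent never
#'   arrives).
#' @export
arrival_times <- function(traj, epsilon = NULL) {
  cfg <- attr(traj, "config")
  if (is.null(cfg)) stop("trajectory lacks a config", call. = FALSE)
  if (is.null(epsilon)) epsilon <- cfg$arrival_epsilon
  stopifnot(epsilon > 0)
  wide_x <- tidyr::pivot_wider(traj[c("step", "agent_id", "x")],
                               names_from = "agent_id", values_from = "x")
  wide_y <- tidyr::pivot_wider(traj[c("step", "agent_id", "y")],
                               names_from = "agent_id", values_from = "y")
  times <- arrival_times_matrix(as.matrix(wide_x[-1]), as.matrix(wide_y[-1]),
                                cfg$L, epsilon)
  tibble::tibble(agent_id = sort(unique(traj$agent_id)), tau = times)
}

#' Min-max normalization of first-arrival times
#'
#' Rescales a sweep's mean first-arrival times to `[0, 1]`:
#' `(tau - min) / (max - min)`. Useful for plotting arrival times alongside
#' success rates on one axis.
#'
#' @param taus Numeric vector with at least two distinct finite values
#'   (`NA`s are carried through).
#' @return Numeric vector of the same length in `[0, 1]` (plus `NA`s).
#' @export
tau_normalize <- function(taus) {
  fin <- taus[is.finite(taus)]
  if (length(unique(fin)) < 2)
    stop("tau normalization needs >= 2 distinct finite values", call. = FALSE)
  (taus - min(fin)) / (max(fin) - min(fin))
}

#' Ensemble statistics over replicate trajectories
#'
#' Reduces a list of replicate runs to the standard observables: the success
#' rate `s` (fraction of successful runs), the mean first-arrival time over
#' successful runs only (`NA` when no run arrives -- reported as missing,
#' never as 0), and the ensemble mean of each run's final-window order
#' parameter. The ensemble counts as coordinated when that mean reaches
#' `coordination_threshold`. Runs are never truncated at arrival, so the
#' order-parameter statistics always use full-length runs.
#'
#' The default task convention, `arrival = "each"`, counts a run successful
#' when every agent enters the `epsilon`-disk around the field centre at some
#' time during the run, and takes the run's first-arrival time as the mean of
#' the agents' individual first arrivals (for one agent this is simply that
#' agent's arrival). `arrival = "simultaneous"` instead requires all agents
#' inside the disk at the same step, as in [first_arrival()] -- a much
#' stricter rule, kept for sensitivity analysis.
#'
#' @param runs List of `pk_trajectory` objects (all with the same shape).
#' @param epsilon Arrival tolerance; default from the first run's config.
#' @param coordination_threshold Cutoff on the mean final-window order
#'   parameter; default from the config.
#' @param window Final fraction of steps to average the order parameter over;
#'   default from the config.
#' @param arrival Task convention: `"each"` (default) or `"simultaneous"`.
#' @return A `pk_ensemble` object; see [tidy()] and [glance()] methods.
#' @export
ensemble_stats <- function(runs, epsilon = NULL, coordination_threshold = NULL,
                           window = NULL,
                           arrival = c("each", "simultaneous")) {
  arrival <- match.arg(arrival)
  stopifnot(length(runs) >= 1)
  cfg <- attr(runs[[1]], "config")
  if (is.null(epsilon)) epsilon <- cfg$arrival_epsilon
  if (is.null(coordination_threshold))
    coordination_threshold <- cfg$coordination_threshold
  if (is.null(window)) window <- cfg$window
  per_run <- purrr::map_dfr(seq_along(runs), function(k) {
    traj <- runs[[k]]
    wide <- lapply(c("x", "y", "theta"), function(v) {
      w <- tidyr::pivot_wider(traj[c("step", "agent_id", v)],
                              names_from = "agent_id",
                              values_from = dplyr::all_of(v))
      as.matrix(w[-1])
    })
    arr <- run_arrival(wide[[1]], wide[[2]], cfg$L, epsilon, arrival)
    tibble::tibble(
      run = k,
      seed = if (is.null(attr(traj, "seed"))) NA_integer_ else attr(traj, "seed"),
      success = arr$success,
      tau = arr$tau,
      va_final = final_window_va(wide[[3]], window)
    )
  })
  new_ensemble(per_run, cfg, epsilon, coordination_threshold, window,
               arrival = arrival)
}

# Shared constructor for ensemble results.
new_ensemble <- function(per_run, cfg, epsilon, coordination_threshold,
                         window, arrival = "each", master_seed = NULL) {
  structure(list(
    runs = per_run,
    config = cfg,
    arrival_epsilon = epsilon,
    coordination_threshold = coordination_threshold,
    window = window,
    arrival = arrival,
    master_seed = master_seed
  ), class = "pk_ensemble")
}

#' @describeIn ensemble_stats Per-run records: one row per replicate with
#'   columns `run`, `seed`, `success`, `tau`, `va_final`.
#' @param x A `pk_ensemble`.
#' @param ... Unused.
#' @export
tidy.pk_ensemble <- function(x, ...) x$runs

#' @describeIn ensemble_stats One-row summary with `n_experiments`, `s`,
#'   `mean_tau`, `mean_va`, `coordinated`.
#' @export
glance.pk_ensemble <- function(x, ...) {
  r <- x$runs
  mean_tau <- if (any(r$success)) mean(r$tau[r$success]) else NA_real_
  mean_va <- mean(r$va_final)
  tibble::tibble(
    n_experiments = nrow(r),
    s = mean(r$success),
    mean_tau = mean_tau,
    mean_va = mean_va,
    coordinated = mean_va >= x$coordination_threshold
  )
}

#' @export
print.pk_ensemble <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<pk_ensemble> %d replicates of %d steps (%d agent%s)\n",
              g$n_experiments, x$config$n_steps, x$config$n_agents,
              if (x$config$n_agents == 1) "" else "s"))
  cat(sprintf("  success rate s = %.3f; mean tau = %s; mean v_a = %.3f (%scoordinated)\n",
              g$s, if (is.na(g$mean_tau)) "NA" else sprintf("%.1f", g$mean_tau),
              g$mean_va, if (g$coordinated) "" else "not "))
  invisible(x)
}
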