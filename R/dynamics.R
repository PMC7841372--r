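#' Wrap angles into (-pi, pi]
#'
#' Reduces any finite angle modulo 2*pi into the half-open interval
#' `(-pi, pi]`; `-pi` maps to `pi`.
#'
#' @param theta Numeric vector of angles in radians.
#' @return Numeric vector of the same length, each element in `(-pi, pi]`.
#' @examples
#' wrap_angle(c(0, 3 * pi / 2, -pi))
#' @export
wrap_angle <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta)))
    stop("`theta` must be finite", call. = FALSE)
  y <- theta - (2 * pi) * floor((theta + pi) / (2 * pi))
  y[y <= -pi] <- pi
  y[y > pi] <- pi
  y
}

#' Skill-modulated self heading update
#'
#' One step of the free heading dynamics: the agent keeps its heading up to a
#' noise kick attenuated by its skill, `theta + xi2 / p`, wrapped to
#' `(-pi, pi]`. High skill means small kicks and near-straight motion.
#'
#' @param theta Current heading (radians).
#' @param xi2 Noise draw, uniform on `[-xi, xi]`.
#' @param p Skill, strictly positive.
#' @return New heading in `(-pi, pi]`.
#' @export
heading_self <- function(theta, xi2, p) {
  if (any(p <= 0)) stop("skill `p` must be positive", call. = FALSE)
  wrap_angle(theta + xi2 / p)
}

#' Minimum-image distance on the periodic square
#'
#' Euclidean distance between two points of the `L`-periodic square under the
#' minimum-image convention: each coordinate displacement is reduced to at
#' most `L/2` by wrapping. The result never exceeds `L / sqrt(2)`.
#'
#' @param a,b Numeric 2-vectors with coordinates in `[0, L)`.
#' @param L Side length.
#' @return Scalar distance.
#' @examples
#' periodic_distance(c(0.1, 0), c(4.9, 0), L = 5) # wraps: 0.2
#' @export
periodic_distance <- function(a, b, L) {
  d <- abs(a - b)
  d <- pmin(d, L - d)
  sqrt(sum(d^2))
}

#' Circular mean heading within the interaction radius
#'
#' The Vicsek alignment target for agent `i`: the two-argument-arctangent
#' circular mean of the headings of every agent (including `i` itself) whose
#' minimum-image distance from agent `i` is at most `r`. With no neighbour
#' besides itself the agent's own heading is returned unchanged.
#'
#' @param agents Data frame with columns `x`, `y`, `theta` (one row per agent).
#' @param i Index of the focal agent.
#' @param r Interaction radius.
#' @param L Side length of the periodic square.
#' @return Mean heading in `(-pi, pi]`.
#' @export
circular_mean_in_radius <- function(agents, i, r, L) {
  stopifnot(nrow(agents) >= 1, i >= 1, i <= nrow(agents))
  d <- vapply(seq_len(nrow(agents)), function(j) {
    periodic_distance(c(agents$x[i], agents$y[i]),
                      c(agents$x[j], agents$y[j]), L)
  }, numeric(1))
  nb <- which(d <= r)
  if (length(nb) <= 1L) return(agents$theta[i])
  atan2(mean(sin(agents$theta[nb])), mean(cos(agents$theta[nb])))
}

#' Mix the self/social and environmental heading terms
#'
#' Combines the self (or social-mean) heading with the gradient heading as
#' `alpha * (theta_base + xi2/p) + beta * (theta_g + xi3/p)`. With the default
#' `mix = "scalar"` each inner term is wrapped to `(-pi, pi]` and the literal
#' weighted sum of the two angle values is wrapped again; `mix = "circular"`
#' instead takes the direction of the weighted sum of the terms' unit vectors.
#'
#' @param theta_base Self heading or circular-mean heading (radians).
#' @param theta_g Gradient heading (radians); ignored when `beta = 0`.
#' @param xi2,xi3 Noise draws, uniform on `[-xi, xi]`.
#' @param p Skill, strictly positive.
#' @param alpha,beta Weights with `alpha + beta = 1`.
#' @param mix `"scalar"` (the model as defined) or `"circular"`.
#' @return New heading in `(-pi, pi]`.
#' @examples
#' heading_update(0.2, 0.6, xi2 = 0.5, xi3 = -0.5, p = 100,
#'                alpha = 0.95, beta = 0.05) # 0.2245
#' @export
heading_update <- function(theta_base, theta_g, xi2, xi3, p, alpha, beta,
                           mix = c("scalar", "circular")) {
  mix <- match.arg(mix)
  if (any(p <= 0)) stop("skill `p` must be positive", call. = FALSE)
  if (abs(alpha + beta - 1) > 1e-12)
    stop("`alpha + beta` must equal 1", call. = FALSE)
  self_term <- wrap_angle(theta_base + xi2 / p)
  env_term <- if (beta == 0) 0 else wrap_angle(theta_g + xi3 / p)
  if (mix == "scalar") {
    wrap_angle(alpha * self_term + beta * env_term)
  } else {
    atan2(alpha * sin(self_term) + beta * sin(env_term),
          alpha * cos(self_term) + beta * cos(env_term))
  }
}

#' Advance a position one step
#'
#' The constant-speed position rule: the agent's perceived position
#' `x + xi1 / p` advances by `kappa` in the direction of the new heading, and
#' both coordinates wrap into `[0, L)`.
#'
#' @param pos Numeric 2-vector, coordinates in `[0, L)`.
#' @param heading New heading (radians, already wrapped).
#' @param xi1 Numeric 2-vector of position-noise draws.
#' @param p Skill, strictly positive.
#' @param kappa Step length.
#' @param L Side length.
#' @return Numeric 2-vector in `[0, L)^2`.
#' @export
position_update <- function(pos, heading, xi1, p, kappa, L) {
  if (any(p <= 0)) stop("skill `p` must be positive", call. = FALSE)
  v <- pos + xi1 / p + kappa * c(cos(heading), sin(heading))
  m <- v - L * floor(v / L)
  m[m < 0] <- m[m < 0] + L
  m[m >= L] <- m[m >= L] - L
  m
}

#' One synchronous update of all agents (scalar reference)
#'
#' Advances every agent one time step with plain R loops: first every new
#' heading is computed from the time-t snapshot, then every position is
#' advanced using the new headings. This is the reference implementation the
#' compiled stepper is tested against; it consumes the same noise stream
#' layout (see [draw_noise()]).
#'
#' @param agents Data frame with columns `x`, `y`, `theta`, `p`.
#' @param cfg A [pk_config()]. `cfg$n_agents` must match `nrow(agents)`.
#' @param draws Noise draws for this single step: numeric vector of length
#'   `nrow(agents) * 4` ordered by agent then (xi2, xi3, xi1x, xi1y). If
#'   `NULL`, fresh draws are taken from the current RNG.
#' @return A tibble like `agents` with updated `x`, `y`, `theta`.
#' @export
step_agents <- function(agents, cfg, draws = NULL) {
  cfg <- validate_config(cfg)
  n <- nrow(agents)
  stopifnot(n == cfg$n_agents)
  if (is.null(draws)) draws <- draw_noise(1L, n, cfg$xi)
  stopifnot(length(draws) == n * 4)
  field <- gaussian_field(cfg$L)

  new_theta <- numeric(n)
  for (i in seq_len(n)) {
    d <- draws[(i - 1L) * 4L + 1:4]
    base <- if (cfg$social_enabled) {
      circular_mean_in_radius(agents, i, cfg$r, cfg$L)
    } else {
      agents$theta[i]
    }
    tg <- if (cfg$env_enabled) {
      gradient_angle(c(agents$x[i], agents$y[i]), field,
                     fallback = agents$theta[i])
    } else {
      0
    }
    new_theta[i] <- heading_update(base, tg, d[1], d[2], agents$p[i],
                                   cfg$alpha, cfg$beta, mix = cfg$mix)
  }
  out <- agents
  for (i in seq_len(n)) {
    d <- draws[(i - 1L) * 4L + 1:4]
    np <- position_update(c(agents$x[i], agents$y[i]), new_theta[i],
                          c(d[3], d[4]), agents$p[i], cfg$kappa, cfg$L)
    out$x[i] <- np[1]
    out$y[i] <- np[2]
    out$theta[i] <- new_theta[i]
  }
  tibble::as_tibble(out)
}

#' Draw initial agent states
#'
#' Positions uniform on `[0, L)^2`, headings uniform on `(-pi, pi]`, drawn in
#' agent order (x, y, theta per agent) from the current RNG.
#'
#' @param cfg A [pk_config()].
#' @return Tibble with columns `agent_id`, `x`, `y`, `theta`, `p`.
#' @export
init_agents <- function(cfg) {
  cfg <- validate_config(cfg)
  p <- skill_vector(cfg)
  n <- cfg$n_agents
  draws <- matrix(runif(3 * n), nrow = n, byrow = TRUE)
  tibble::tibble(
    agent_id = seq_len(n),
    x = draws[, 1] * cfg$L,
    y = draws[, 2] * cfg$L,
    theta = draws[, 3] * 2 * pi - pi, # uniform on (-pi, pi)
    p = p
  )
}

# Internal fast-path run: returns snapshot matrices, not a tibble.
# x0/y0/theta0 may be supplied to bypass random initialisation.
sim_run <- function(cfg, seed = NULL, engine = c("compiled", "reference"),
                    init = NULL, draws = NULL) {
  engine <- match.arg(engine)
  cfg <- validate_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- init_agents(cfg)
  if (is.null(draws)) draws <- draw_noise(cfg$n_steps, cfg$n_agents, cfg$xi)
  p <- rep_len(init$p, cfg$n_agents)
  if (engine == "compiled") {
    sim_core_cpp(init$x, init$y, init$theta, p, draws, cfg$n_steps,
                 cfg$L, cfg$kappa, cfg$alpha, cfg$beta, cfg$r,
                 cfg$env_enabled, cfg$social_enabled,
                 if (cfg$mix == "scalar") 0L else 1L)
  } else {
    n <- cfg$n_agents
    X <- matrix(NA_real_, cfg$n_steps + 1L, n)
    Y <- matrix(NA_real_, cfg$n_steps + 1L, n)
    TH <- matrix(NA_real_, cfg$n_steps + 1L, n)
    cur <- init
    X[1, ] <- cur$x; Y[1, ] <- cur$y; TH[1, ] <- cur$theta
    for (t in seq_len(cfg$n_steps)) {
      idx <- ((t - 1L) * n * 4L + 1L):(t * n * 4L)
      cur <- step_agents(cur, cfg, draws[idx])
      X[t + 1L, ] <- cur$x; Y[t + 1L, ] <- cur$y; TH[t + 1L, ] <- cur$theta
    }
    list(x = X, y = Y, theta = TH)
  }
}

#' Simulate a full trajectory
#'
#' Runs the model for `cfg$n_steps` synchronous updates from random initial
#' conditions (positions uniform on the square, headings uniform on
#' `(-pi, pi]`) and returns every snapshot, including the initial one, as a
#' tidy tibble. The same `(cfg, seed)` pair always reproduces the identical
#' trajectory.
#'
#' @param cfg A [pk_config()].
#' @param seed RNG seed; defaults to `cfg$seed`. `NULL` continues the current
#'   RNG state.
#' @param engine `"compiled"` uses the C++ stepper; `"reference"` the scalar
#'   R implementation (identical results, orders of magnitude slower).
#' @param init Optional data frame with columns `x`, `y`, `theta`, `p` (one
#'   row per agent) fixing the initial state instead of drawing it; useful
#'   for worked examples and noise-free checks.
#' @return A `pk_trajectory`: tibble with columns `step` (0-based),
#'   `agent_id`, `x`, `y`, `theta`, carrying the configuration and seed as
#'   attributes.
#' @examples
#' traj <- simulate_agents(pk_config(n_steps = 100, p = 100), seed = 1)
#' head(traj)
#' @export
simulate_agents <- function(cfg, seed = cfg$seed,
                            engine = c("compiled", "reference"),
                            init = NULL) {
  engine <- match.arg(engine)
  cfg <- validate_config(cfg)
  mats <- sim_run(cfg, seed = seed, engine = engine, init = init)
  as_trajectory(mats, cfg, seed)
}

# Assemble the tidy trajectory from snapshot matrices.
as_trajectory <- function(mats, cfg, seed = NULL) {
  n <- ncol(mats$theta)
  steps <- nrow(mats$theta) - 1L
  out <- tibble::tibble(
    step = rep(0:steps, times = n),
    agent_id = rep(seq_len(n), each = steps + 1L),
    x = as.vector(mats$x),
    y = as.vector(mats$y),
    theta = as.vector(mats$theta)
  )
  out <- dplyr::arrange(out, .data$step, .data$agent_id)
  structure(out, config = cfg, seed = seed,
            class = c("pk_trajectory", class(out)))
}

#' Heading-increment standard deviation of a trajectory
#'
#' Sample standard deviation of the wrapped step-to-step heading increments,
#' pooled over agents. For the free dynamics the increments are i.i.d.
#' uniform on `[-xi/p, xi/p]`, so this estimates `xi / (p * sqrt(3))`.
#'
#' @param traj A `pk_trajectory`.
#' @return Scalar standard deviation (radians).
#' @export
heading_increment_sd <- function(traj) {
  inc <- dplyr::group_by(traj, .data$agent_id)
  inc <- dplyr::mutate(inc, d = wrap_angle_diff(.data$theta))
  inc <- dplyr::ungroup(inc)
  sd(inc$d, na.rm = TRUE)
}

# Wrapped difference theta_t - theta_{t-1} in (-pi, pi]; NA for the first row.
wrap_angle_diff <- function(theta) {
  d <- c(NA_real_, diff(theta))
  ok <- !is.na(d)
  d[ok] <- wrap_angle(d[ok])
  d
}
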