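#' Build a simulation configuration
#'
#' Collects every model parameter into a validated `pk_config` object. The
#' defaults are the reference conditions used throughout: a 5 x 5 periodic
#' square, step length 0.05 per time step, noise half-width 0.5, interaction
#' radius 1, and 2500 time steps.
#'
#' The skill parameter `p` divides every noise draw, so large `p` means
#' accurate proprioception (near-deterministic motion) and small `p` means
#' erratic motion. `alpha` and `beta` weight the self/social heading term and
#' the environmental (gradient) heading term; they must sum to 1. The
#' environmental coupling requires `env_enabled = TRUE` (and `beta > 0` to
#' have any effect); heading alignment between agents requires
#' `social_enabled = TRUE` and at least two agents.
#'
#' @param L Side length of the periodic square (length units).
#' @param kappa Step length per time step (length units).
#' @param xi Noise half-width; all noise draws are uniform on `[-xi, xi]`.
#' @param p Skill, strictly positive; scalar (shared) or one value per agent.
#' @param alpha,beta Heading-mixing weights, `alpha + beta = 1`, both in
#'   `[0, 1]`. `beta` must be 0 when `env_enabled` is `FALSE`.
#' @param r Interaction radius for heading alignment (length units).
#' @param n_steps Number of time steps (at least 1).
#' @param n_agents Number of agents (at least 1; the studied cases are 1 and 2).
#' @param env_enabled Couple headings to the concentration-field gradient?
#' @param social_enabled Align headings with neighbours within `r`?
#' @param arrival_epsilon Arrival tolerance: a run "arrives" at the first step
#'   where every agent is within this plain Euclidean distance of the field
#'   centre `(L/2, L/2)`.
#' @param coordination_threshold An ensemble counts as coordinated when its
#'   mean final-window order parameter reaches this cutoff.
#' @param window Fraction of the run (taken from the end) over which the
#'   order parameter is averaged.
#' @param mix `"scalar"` mixes the two heading terms as the literal weighted
#'   sum of angle values (each term and the result wrapped to `(-pi, pi]`);
#'   `"circular"` mixes their unit vectors instead. `"scalar"` is the model as
#'   defined; the circular variant is provided for sensitivity checks.
#' @param seed Optional RNG seed stored with the configuration.
#' @return A `pk_config` list.
#' @examples
#' cfg <- pk_config(n_agents = 2, alpha = 0.95, beta = 0.05,
#'                  env_enabled = TRUE, p = 50)
#' cfg
#' @export
pk_config <- function(L = 5, kappa = 0.05, xi = 0.5, p = 10,
                      alpha = 1, beta = 0, r = 1,
                      n_steps = 2500, n_agents = 1,
                      env_enabled = beta > 0,
                      social_enabled = n_agents > 1,
                      arrival_epsilon = 0.1,
                      coordination_threshold = 0.95,
                      window = 0.1,
                      mix = c("scalar", "circular"),
                      seed = NULL) {
  cfg <- structure(list(
    L = as.numeric(L), kappa = as.numeric(kappa), xi = as.numeric(xi),
    p = as.numeric(p), alpha = as.numeric(alpha), beta = as.numeric(beta),
    r = as.numeric(r), n_steps = as.integer(n_steps),
    n_agents = as.integer(n_agents),
    env_enabled = isTRUE(env_enabled), social_enabled = isTRUE(social_enabled),
    arrival_epsilon = as.numeric(arrival_epsilon),
    coordination_threshold = as.numeric(coordination_threshold),
    window = as.numeric(window),
    mix = match.arg(mix),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "pk_config")
  validate_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks every invariant of [pk_config()] and returns the configuration
#' invisibly unchanged, or raises an error naming the offending field.
#'
#' @param cfg A `pk_config` object (or a bare list with the same fields).
#' @return `cfg`, invisibly classed as `pk_config`.
#' @export
validate_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
  }
  num1 <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      fail(field, "must be a single finite number")
    v
  }
  if (num1("L") <= 0) fail("L", "must be > 0")
  if (num1("kappa") <= 0) fail("kappa", "must be > 0")
  if (num1("xi") < 0) fail("xi", "must be >= 0")
  if (num1("r") <= 0) fail("r", "must be > 0")
  if (!is.numeric(cfg$p) || any(!is.finite(cfg$p)) || any(cfg$p <= 0))
    fail("p", "must be finite and > 0 (skill divides the noise)")
  if (!length(cfg$p) %in% c(1L, cfg$n_agents))
    fail("p", "must be a scalar or have one value per agent")
  a <- num1("alpha"); b <- num1("beta")
  if (a < 0 || a > 1 || b < 0 || b > 1) fail("alpha/beta", "must lie in [0, 1]")
  if (abs(a + b - 1) > 1e-12) fail("alpha/beta", "must satisfy alpha + beta = 1")
  if (cfg$n_steps < 0L) fail("n_steps", "must be >= 0")
  if (cfg$n_agents < 1L) fail("n_agents", "must be >= 1")
  if (!cfg$env_enabled && b != 0)
    fail("beta", "must be 0 when env_enabled is FALSE")
  if (num1("arrival_epsilon") <= 0) fail("arrival_epsilon", "must be > 0")
  ct <- num1("coordination_threshold")
  if (ct <= 0 || ct > 1) fail("coordination_threshold", "must lie in (0, 1]")
  w <- num1("window")
  if (w <= 0 || w > 1) fail("window", "must lie in (0, 1]")
  if (!cfg$mix %in% c("scalar", "circular")) fail("mix", "is unknown")
  invisible(structure(cfg, class = "pk_config"))
}

#' @export
print.pk_config <- function(x, ...) {
  cat("<pk_config>\n")
  cat(sprintf("  space L = %g, step kappa = %g, noise xi = %g\n",
              x$L, x$kappa, x$xi))
  cat(sprintf("  agents: %d, skill p = %s, radius r = %g\n",
              x$n_agents, paste(x$p, collapse = ", "), x$r))
  cat(sprintf("  weights: alpha = %g, beta = %g (env %s, social %s, %s mix)\n",
              x$alpha, x$beta,
              if (x$env_enabled) "on" else "off",
              if (x$social_enabled) "on" else "off", x$mix))
  cat(sprintf("  horizon: %d steps; arrival eps = %g; v_a cutoff = %g over final %g\n",
              x$n_steps, x$arrival_epsilon, x$coordination_threshold, x$window))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Per-agent skill vector
#' @param cfg A `pk_config`.
#' @return Numeric vector of length `n_agents`.
#' @keywords internal
skill_vector <- function(cfg) rep_len(cfg$p, cfg$n_agents)

#' Read a configuration from a JSON file
#'
#' Missing fields take the [pk_config()] defaults; unknown keys are dropped
#' with a warning; invariant violations are reported with the field name.
#'
#' @param path Path to a JSON file holding a flat object of config fields.
#' @return A validated `pk_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw) == 0) raw <- list()
  known <- names(formals(pk_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "),
            call. = FALSE)
    raw <- raw[intersect(names(raw), known)]
  }
  do.call(pk_config, raw)
}

#' Write a configuration to a JSON file
#'
#' The file round-trips: `load_config(save_config(cfg, path))` reproduces
#' `cfg` exactly.
#'
#' @param cfg A `pk_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  fields <- Filter(Negate(is.null), unclass(cfg))
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
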