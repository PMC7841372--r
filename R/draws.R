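#' Draw the full noise stream for one run
#'
#' All stochasticity in a run lives in one flat vector of uniform(-xi, xi)
#' variates, drawn up front from R's RNG. The stream is ordered by time step,
#' then agent, then draw kind -- (xi2, xi3, xi1x, xi1y) -- and the same four
#' draws are consumed every step whether or not the environmental coupling is
#' active, so identical seeds give identical streams across model variants and
#' a scalar reference implementation can replay a compiled run draw-for-draw.
#'
#' xi2 perturbs the self/social heading term, xi3 the gradient heading term,
#' and (xi1x, xi1y) the two position coordinates; each enters the dynamics
#' divided by the agent's skill p.
#'
#' @param n_steps Number of time steps.
#' @param n_agents Number of agents.
#' @param xi Noise half-width; draws are uniform on `[-xi, xi]`.
#' @return Numeric vector of length `n_steps * n_agents * 4`.
#' @seealso [noise_index()] for the position of a given draw in the stream.
#' @export
draw_noise <- function(n_steps, n_agents, xi) {
  stopifnot(n_steps >= 0, n_agents >= 1, xi >= 0)
  if (xi == 0) return(numeric(n_steps * n_agents * 4))
  runif(n_steps * n_agents * 4, -xi, xi)
}

#' Locate a draw in a noise stream
#'
#' @param step Time step, 1-based (the step producing snapshot `step`).
#' @param agent Agent index, 1-based.
#' @param kind One of `"xi2"`, `"xi3"`, `"xi1x"`, `"xi1y"`.
#' @param n_agents Number of agents in the stream.
#' @return Integer index into the vector returned by [draw_noise()].
#' @export
noise_index <- function(step, agent, kind = c("xi2", "xi3", "xi1x", "xi1y"),
                        n_agents) {
  kind <- match.arg(kind)
  k <- match(kind, c("xi2", "xi3", "xi1x", "xi1y"))
  ((step - 1L) * n_agents + (agent - 1L)) * 4L + k
}
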