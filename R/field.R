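#' The Gaussian concentration field
#'
#' A static, unit-variance, circularly symmetric Gaussian concentration bump
#' centred at `(L/2, L/2)`:
#' \deqn{N(x, y) = \frac{1}{2\pi} \exp\!\left(-\frac{(x - L/2)^2 + (y - L/2)^2}{2}\right).}
#' The field is defined on the single cell `[0, L]^2`; periodic images are
#' not summed, so an agent that wraps across a boundary simply sees the
#' single-bump field at its new coordinates.
#'
#' @param L Side length of the square.
#' @return A `pk_field` list with elements `L`, `center`, `variance`.
#' @export
gaussian_field <- function(L = 5) {
  stopifnot(is.numeric(L), length(L) == 1, L > 0)
  structure(list(L = L, center = c(L / 2, L / 2), variance = 1),
            class = "pk_field")
}

#' @export
print.pk_field <- function(x, ...) {
  cat(sprintf("<pk_field> Gaussian bump on [0, %g]^2, centre (%g, %g), variance %g\n",
              x$L, x$center[1], x$center[2], x$variance))
  invisible(x)
}

# Coerce positions to an n x 2 matrix.
pos_matrix <- function(pos) {
  if (is.matrix(pos)) return(pos)
  if (is.data.frame(pos)) return(cbind(pos$x, pos$y))
  matrix(pos, ncol = 2)
}

#' Concentration at a position
#'
#' @param pos Numeric 2-vector, n x 2 matrix, or data frame with `x`, `y`.
#' @param field A [gaussian_field()].
#' @return Numeric vector of concentrations, one per position.
#' @examples
#' f <- gaussian_field(5)
#' concentration(f$center, f) # 1 / (2 * pi)
#' @export
concentration <- function(pos, field = gaussian_field()) {
  m <- pos_matrix(pos)
  dx <- m[, 1] - field$center[1]
  dy <- m[, 2] - field$center[2]
  exp(-(dx^2 + dy^2) / 2) / (2 * pi)
}

#' Analytic gradient of the concentration field
#'
#' The exact gradient `g = (dN/dx, dN/dy) = -(pos - centre) * N(pos)`; it
#' points toward the centre everywhere and vanishes exactly there.
#'
#' @inheritParams concentration
#' @return An n x 2 matrix of gradient vectors (columns `gx`, `gy`).
#' @export
field_gradient <- function(pos, field = gaussian_field()) {
  m <- pos_matrix(pos)
  n <- concentration(m, field)
  cbind(gx = -(m[, 1] - field$center[1]) * n,
        gy = -(m[, 2] - field$center[2]) * n)
}

#' Gradient heading
#'
#' The heading of the normalized gradient, `atan2(gy, gx)` -- the direction of
#' steepest concentration increase, which is exactly the direction from the
#' position toward the field centre. Where the gradient is degenerate
#' (`||g|| <= 1e-12`, i.e. at or numerically at the centre) the supplied
#' fallback heading is returned so the heading update stays well defined.
#'
#' @param pos Numeric 2-vector, n x 2 matrix, or data frame with `x`, `y`.
#' @param field A [gaussian_field()].
#' @param fallback Heading(s) returned at degenerate positions (radians).
#' @return Numeric vector of headings in `(-pi, pi]`.
#' @examples
#' f <- gaussian_field(5)
#' gradient_angle(c(f$L / 2 + 1, f$L / 2), f) # pi: toward the centre
#' @export
gradient_angle <- function(pos, field = gaussian_field(), fallback = 0) {
  m <- pos_matrix(pos)
  g <- field_gradient(m, field)
  gnorm <- unname(sqrt(g[, 1]^2 + g[, 2]^2))
  # "+ 0" turns IEEE negative zero into +0 so axis-aligned angles land on
  # pi (not -pi), keeping results inside (-pi, pi]
  out <- unname(atan2(g[, 2] + 0, g[, 1] + 0))
  bad <- gnorm <= 1e-12
  if (any(bad)) out[bad] <- rep_len(fallback, nrow(m))[bad]
  out
}

#' Sample the field on a regular grid
#'
#' Tabulates concentration and gradient on an `n x n` grid over `[0, L]^2`,
#' ready for plotting or CSV export.
#'
#' @param field A [gaussian_field()].
#' @param n Grid points per axis.
#' @return Tibble with columns `x`, `y`, `N`, `gx`, `gy`.
#' @export
field_grid <- function(field = gaussian_field(), n = 41) {
  ax <- seq(0, field$L, length.out = n)
  grid <- tidyr::expand_grid(x = ax, y = ax)
  g <- field_gradient(grid, field)
  dplyr::mutate(grid, N = concentration(grid, field),
                gx = g[, 1], gy = g[, 2])
}
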