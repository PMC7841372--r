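#' Plot a trajectory
#'
#' Path of each agent over the periodic square, coloured by agent, with the
#' field centre marked. Wrap-around steps appear as long jumps, as in the
#' usual periodic-boundary plots.
#'
#' @param object A `pk_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pk_trajectory <- function(object, ...) {
  cfg <- attr(object, "config")
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y,
                                       colour = factor(.data$agent_id))) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::geom_point(data = dplyr::filter(object, .data$step == 0),
                        shape = 1, size = 2) +
    ggplot2::annotate("point", x = cfg$L / 2, y = cfg$L / 2, shape = 3) +
    ggplot2::coord_fixed(xlim = c(0, cfg$L), ylim = c(0, cfg$L)) +
    ggplot2::labs(colour = "agent", x = "x", y = "y") +
    ggplot2::theme_minimal()
}

#' Plot heading time series of a trajectory
#'
#' @param traj A `pk_trajectory`.
#' @return A ggplot object: heading against time, one line per agent.
#' @export
plot_headings <- function(traj) {
  ggplot2::ggplot(traj, ggplot2::aes(.data$step, .data$theta,
                                     colour = factor(.data$agent_id))) +
    ggplot2::geom_line() +
    ggplot2::labs(colour = "agent", x = "t", y = expression(theta(t))) +
    ggplot2::theme_minimal()
}

#' Plot the concentration field and its gradient
#'
#' Concentration raster with a down-sampled gradient vector overlay.
#'
#' @param field A [gaussian_field()].
#' @param n Raster resolution per axis.
#' @param arrows Arrows per axis in the overlay.
#' @return A ggplot object.
#' @export
plot_field <- function(field = gaussian_field(), n = 81, arrows = 15) {
  dense <- field_grid(field, n)
  coarse <- field_grid(field, arrows)
  scale <- field$L / arrows
  ggplot2::ggplot(dense, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$N)) +
    ggplot2::geom_segment(
      data = dplyr::mutate(coarse,
                           len = pmax(sqrt(.data$gx^2 + .data$gy^2), 1e-15)),
      ggplot2::aes(xend = .data$x + scale * .data$gx / .data$len,
                   yend = .data$y + scale * .data$gy / .data$len),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.1, "cm")),
      linewidth = 0.2, colour = "white"
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "N(x, y)") +
    ggplot2::theme_minimal()
}

#' Plot a sweep
#'
#' Success rate, normalized first-arrival time, and mean order parameter
#' against skill, faceted by observable and coloured by the `(alpha, beta)`
#' weighting (when present in the sweep).
#'
#' @param object A `pk_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pk_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = dplyr::any_of(c("s", "tau_norm", "mean_va")),
    names_to = "observable", values_to = "value"
  )
  long$weights <- sprintf("alpha=%g, beta=%g", long$alpha, long$beta)
  ggplot2::ggplot(long, ggplot2::aes(.data$p1, .data$value,
                                     colour = .data$weights)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "skill p", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
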