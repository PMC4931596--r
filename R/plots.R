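# Quick-look ggplot2 graphics for fields, defects and trajectories.

#' Plot a director field
#'
#' Short line segments along the local director, coloured by the scalar
#' order parameter where available.
#'
#' @param object A `director_field` tibble.
#' @param every Draw every `every`-th cell in each direction.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.director_field <- function(object, every = 2, ...) {
  g <- field_grid(object)
  d <- object[object$defined & !is.na(object$theta) &
                (object$ix %% every == 0) & (object$iy %% every == 0), ]
  len <- g$cell_size * every * 0.45
  d$xend <- d$x + len * cos(d$theta); d$yend <- d$y + len * sin(d$theta)
  d$xstart <- d$x - len * cos(d$theta); d$ystart <- d$y - len * sin(d$theta)
  pl <- ggplot2::ggplot(d)
  if ("S" %in% names(d)) {
    pl <- pl + ggplot2::geom_segment(
      ggplot2::aes(x = .data$xstart, y = .data$ystart, xend = .data$xend,
                   yend = .data$yend, colour = .data$S)) +
      ggplot2::scale_colour_viridis_c(limits = c(0, NA))
  } else {
    pl <- pl + ggplot2::geom_segment(
      ggplot2::aes(x = .data$xstart, y = .data$ystart,
                   xend = .data$xend, yend = .data$yend))
  }
  pl + ggplot2::coord_equal() + ggplot2::theme_minimal() +
    ggplot2::labs(x = "x (D)", y = "y (D)")
}

#' Overlay detected defects on a director field plot
#'
#' @param d A `director_field`.
#' @param defects Output of [detect_defects()].
#' @param ... Passed to [autoplot.director_field()].
#' @return A ggplot object.
#' @export
plot_defects <- function(d, defects, ...) {
  pl <- autoplot.director_field(d, ...)
  if (nrow(defects) > 0) {
    defects$label <- sprintf("%+.1f", defects$charge)
    pl <- pl + ggplot2::geom_point(
      data = defects,
      ggplot2::aes(x = .data$x, y = .data$y),
      colour = "red", shape = 21, size = 3, stroke = 1.2) +
      ggplot2::geom_text(data = defects,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      label = .data$label),
                         vjust = -1, colour = "red", size = 3)
  }
  pl
}

#' Plot the equilibration series of a trajectory
#'
#' @param object An `mc_trajectory`.
#' @param ... Unused.
#' @return A ggplot object of lambda_max against sweep.
#' @export
autoplot.mc_trajectory <- function(object, ...) {
  ggplot2::ggplot(object$order,
                  ggplot2::aes(x = .data$sweep, y = .data$lambda_max)) +
    ggplot2::geom_line() + ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "sweep", y = expression(lambda[max]))
}
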