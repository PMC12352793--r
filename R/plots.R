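#' Phase portrait of the replicator system
#'
#' Draws the replicator vector field on the unit square, the rest points
#' coloured by stability class, and (when present) the interior saddle
#' with the straight-edged F-T-G polyline separating the analytic
#' basin proxy of mutual cooperation from that of mutual competition.
#'
#' @param params a [game_params()] object.
#' @param n_arrows arrows per axis for the vector field.
#' @return A ggplot object.
#' @examples
#' plot_phase_portrait(baseline_params())
#' @export
plot_phase_portrait <- function(params, n_arrows = 15) {
  stopifnot(inherits(params, "game_params"))
  coords <- seq(0.02, 0.98, length.out = n_arrows)
  field <- tidyr::expand_grid(x = coords, y = coords)
  d <- replicator_rhs(params, field$x, field$y)
  len <- sqrt(d$dx_dt^2 + d$dy_dt^2)
  len[len == 0] <- 1
  step <- 0.35 / n_arrows
  field$xend <- field$x + step * d$dx_dt / len
  field$yend <- field$y + step * d$dy_dt / len
  eq <- find_equilibria(params)
  gg <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = field,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.1, "cm")),
      colour = "grey55", linewidth = 0.3
    )
  sp <- saddle_point(params)
  if (isTRUE(sp$valid)) {
    sep <- tibble::tibble(x = c(0, sp$x_star, 1),
                          y = c(1, sp$y_star, 0))
    gg <- gg + ggplot2::geom_path(
      data = sep, ggplot2::aes(x = .data$x, y = .data$y),
      linetype = "dashed", colour = "black"
    )
  }
  gg +
    ggplot2::geom_point(
      data = eq,
      ggplot2::aes(x = .data$x, y = .data$y,
                   colour = .data$classification),
      size = 3
    ) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "x (P[superior hospital cooperates])",
      y = "y (P[subordinate hospital cooperates])",
      colour = "stability"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ehr_trajectory <- function(object, type = c("phase", "time"), ...) {
  type <- match.arg(type)
  tb <- tidy(object)
  if (type == "phase") {
    ggplot2::ggplot(tb, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_path() +
      ggplot2::geom_point(data = tb[1, ], shape = 1, size = 3) +
      ggplot2::geom_point(data = tb[nrow(tb), ], shape = 16, size = 3) +
      ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
      ggplot2::labs(x = "x", y = "y",
                    title = paste("terminal:", attr(object, "terminal"))) +
      ggplot2::theme_minimal()
  } else {
    long <- tidyr::pivot_longer(tb, c("x", "y"),
                                names_to = "player", values_to = "prob")
    ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$prob,
                                       colour = .data$player)) +
      ggplot2::geom_line() +
      ggplot2::ylim(0, 1) +
      ggplot2::labs(x = "time", y = "cooperation probability") +
      ggplot2::theme_minimal()
  }
}

#' @export
autoplot.ehr_sweep <- function(object, ...) {
  tb <- tibble::as_tibble(object)
  long <- tidyr::pivot_longer(tb, c("x_final", "y_final"),
                              names_to = "player", values_to = "final")
  gg <- ggplot2::ggplot(long,
                        ggplot2::aes(x = .data$value, y = .data$final,
                                     colour = .data$player)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$terminal)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = unique(tb$parameter), y = "final cooperation prob.") +
    ggplot2::theme_minimal()
  flip <- attr(object, "flip_interval")
  if (!is.null(flip)) {
    gg <- gg + ggplot2::geom_vline(xintercept = mean(flip),
                                   linetype = "dotted")
  }
  gg
}

#' @export
autoplot.ehr_basin_grid <- function(object, ...) {
  tb <- tibble::as_tibble(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$x0, y = .data$y0,
                                   fill = .data$terminal)) +
    ggplot2::geom_tile() +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "initial x", y = "initial y", fill = "terminal") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
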