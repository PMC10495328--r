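# ggplot2 visualizations of the result objects.

#' @export
autoplot.os_parallelism <- function(object, ...) {
  df <- object$table %>%
    tidyr::pivot_longer(
      cols = dplyr::ends_with(c("_mean", "_sd")),
      names_to = c("setup", ".value"), names_pattern = "(.*)_(mean|sd)"
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$location, y = .data$mean,
    color = .data$setup, group = .data$setup
  )) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = pmax(0, .data$mean - .data$sd), ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.45), size = 0.3
    ) +
    ggplot2::facet_wrap(~jaw) +
    ggplot2::labs(
      x = "adjacent-tooth location", y = "|angulation difference| (degrees)",
      color = "setup",
      title = "Adjacent-tooth root parallelism by setup"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.os_exposure <- function(object, ...) {
  df <- object$means %>%
    tidyr::pivot_longer(
      cols = dplyr::ends_with(c("_mean", "_sd")),
      names_to = c("setup", ".value"), names_pattern = "(.*)_(mean|sd)"
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$type, y = .data$mean, fill = .data$setup)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::facet_grid(side ~ jaw) +
    ggplot2::labs(
      x = "tooth type", y = "combined root exposure (mm)", fill = "setup",
      title = "Mean root exposure by setup"
    ) +
    ggplot2::theme_minimal()
}

#' Occlusal-view plot of an arch's landmarks
#'
#' Top view (occlusal plane projection) of the M/D/A landmarks of one
#' patient / jaw / condition, with the long-axis projection drawn from each
#' M-D midpoint to its apex point.
#'
#' @param landmarks landmark tibble (columns `fdi`, `M_x`..`A_z`).
#' @return a ggplot object.
#' @export
plot_arch <- function(landmarks) {
  seg <- landmarks %>%
    dplyr::mutate(
      mid_x = (.data$M_x + .data$D_x) / 2,
      mid_y = (.data$M_y + .data$D_y) / 2
    )
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$M_x, y = .data$M_y, xend = .data$D_x, yend = .data$D_y),
      color = "grey50"
    ) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$mid_x, y = .data$mid_y, xend = .data$A_x, yend = .data$A_y),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")), color = "steelblue"
    ) +
    ggplot2::geom_text(
      ggplot2::aes(x = .data$mid_x, y = .data$mid_y, label = .data$fdi),
      size = 2.5, vjust = -1
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", title = "Occlusal view: M-D segments and apex offsets") +
    ggplot2::theme_minimal()
}
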