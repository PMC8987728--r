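#' Plot a corridor result
#'
#' Draws the input signals (thin grey), the corridor envelope (filled
#' band), the inner/outer corridor polylines, and the characteristic
#' average on top.
#'
#' @param object A `corridor_result`.
#' @param show_signals Draw the input signals underneath (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.corridor_result <- function(object, show_signals = TRUE, ...) {
  p <- ggplot2::ggplot()
  if (show_signals) {
    p <- p + ggplot2::geom_path(
      data = object$signals,
      ggplot2::aes(.data$x, .data$y, group = .data$signal),
      colour = "grey65", linewidth = 0.3
    )
  }
  p +
    ggplot2::geom_polygon(
      data = object$envelope, ggplot2::aes(.data$x, .data$y),
      fill = "goldenrod1", alpha = 0.35
    ) +
    ggplot2::geom_path(
      data = object$inner, ggplot2::aes(.data$x, .data$y),
      colour = "goldenrod3", linewidth = 0.5
    ) +
    ggplot2::geom_path(
      data = object$outer, ggplot2::aes(.data$x, .data$y),
      colour = "goldenrod3", linewidth = 0.5
    ) +
    ggplot2::geom_path(
      data = object$average, ggplot2::aes(.data$x, .data$y),
      colour = "black", linewidth = 0.8
    ) +
    ggplot2::labs(
      x = "x", y = "y",
      title = sprintf(
        "Characteristic average and %.1f%% corridors", 100 * object$config$p
      )
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.corridor_result <- function(x, ...) {
  print(autoplot(x, ...))
  invisible(x)
}
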