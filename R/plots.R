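#' @keywords internal quiver layer of a force-field tibble
#' @noRd
force_quiver_plot <- function(field, mask = NULL, title = NULL) {
  mag <- sqrt(field$fx^2 + field$fy^2)
  sc <- if (max(mag) > 0) 0.06 * max(field$x_um) / max(mag) else 1
  p <- ggplot2::ggplot()
  if (!is.null(mask)) {
    px <- mask$pixel_size
    edge <- which(mask$raster &
                    !(shift_rows(mask$raster, 1) & shift_rows(mask$raster, -1) &
                        shift_cols(mask$raster, 1) & shift_cols(mask$raster, -1)),
                  arr.ind = TRUE)
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(x = (edge[, 2] - 1) * px, y = (edge[, 1] - 1) * px),
      ggplot2::aes(x = .data$x, y = .data$y),
      size = 0.1, colour = "grey60")
  }
  pts <- field[sqrt(field$fx^2 + field$fy^2) > 0, ]
  p +
    ggplot2::geom_segment(
      data = pts,
      ggplot2::aes(x = .data$x_um, y = .data$y_um,
                   xend = .data$x_um + sc * .data$fx,
                   yend = .data$y_um + sc * .data$fy,
                   colour = sqrt(.data$fx^2 + .data$fy^2)),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.1, "cm"))) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c(name = "|f|") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

#' Quiver plot of an estimated traction force field
#' @param object a `btfe_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.btfe_fit <- function(object, ...) {
  force_quiver_plot(object$forces, object$mask, "Bayesian traction estimate")
}

#' Quiver plot of a baseline traction estimate
#' @param object a `baseline_fit` from [tfm_baseline()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.baseline_fit <- function(object, ...) {
  force_quiver_plot(object$forces, object$mask,
                    paste(object$method, "traction estimate"))
}

#' Quiver plot of a synthetic dataset's true forces and bead displacements
#' @param object a `tfm_dataset`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.tfm_dataset <- function(object, ...) {
  p <- force_quiver_plot(object$true_forces, object$mask, "Synthetic dataset")
  p + ggplot2::geom_segment(
    data = object$beads,
    ggplot2::aes(x = .data$x_um, y = .data$y_um,
                 xend = .data$x_um + .data$ux_um,
                 yend = .data$y_um + .data$uy_um),
    colour = "red", linewidth = 0.2)
}

#' Benchmark metric versus bead density, mean with standard-error bars
#'
#' @param bench tibble from [run_benchmark()].
#' @param metric one of "auc", "dtm", "dtmb".
#' @return a ggplot object, faceted by cell.
#' @export
plot_benchmark <- function(bench, metric = c("auc", "dtm", "dtmb")) {
  metric <- match.arg(metric)
  s <- summarize_benchmark(bench)
  mcol <- paste0(metric, "_mean")
  ecol <- paste0(metric, "_se")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$density, y = .data[[mcol]],
                                  colour = .data$algorithm)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data[[mcol]] - .data[[ecol]],
      ymax = .data[[mcol]] + .data[[ecol]])) +
    ggplot2::facet_wrap(~cell) +
    ggplot2::labs(x = "bead density (per um^2)", y = toupper(metric)) +
    ggplot2::theme_minimal()
}
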