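#' Plot a height map, optionally with its traced skeleton
#'
#' @param hm a [height_map].
#' @param trace optional `molecule_trace` overlaid in red.
#' @return a ggplot object.
#' @export
plot_height_map <- function(hm, trace = NULL) {
  stopifnot(inherits(hm, "height_map"))
  df <- tidyr::expand_grid(row = seq_len(nrow(hm$heights)),
                           col = seq_len(ncol(hm$heights)))
  df$height <- as.vector(t(hm$heights))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col * hm$rx,
                                        y = .data$row * hm$ry,
                                        fill = .data$height)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "height (nm)") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)")
  if (!is.null(trace)) {
    sk <- tibble::tibble(x = trace$skeleton_px[, 2] * hm$rx,
                         y = trace$skeleton_px[, 1] * hm$ry)
    p <- p + ggplot2::geom_point(data = sk,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 inherit.aes = FALSE, colour = "red",
                                 size = 0.2)
  }
  p
}

#' Plot a titration with its interpolated C50
#'
#' @param table titration tibble (as accepted by [c50()]).
#' @param result optional `c50_result` to mark on the plot.
#' @return a ggplot object.
#' @export
plot_titration <- function(table, result = NULL) {
  if (!"replicate" %in% names(table)) table$replicate <- 1L
  p <- ggplot2::ggplot(table, ggplot2::aes(x = .data$concentration_nM,
                                           y = .data$fraction_bound,
                                           group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "protein (nM)", y = "fraction bound")
  if (!is.null(result)) {
    p <- p + ggplot2::geom_vline(xintercept = result$c50, colour = "red")
  }
  p
}

#' @export
autoplot.decay_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_counts)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "time (s)", y = "mean photon counts / pixel",
                  subtitle = sprintf("k = %.3g s^-1", object$k))
}

#' @export
autoplot.roi_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$normalized)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "normalized mean intensity")
}

#' @export
autoplot.condensate_morphology <- function(object, ...) {
  rays <- object$rays[!object$rays$excluded, ]
  ggplot2::ggplot(rays, ggplot2::aes(x = .data$angle_deg,
                                     y = .data$thickness_nm)) +
    ggplot2::geom_col(width = 8) +
    ggplot2::geom_hline(yintercept = object$halo_mean_nm, colour = "red") +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = "halo thickness (nm)")
}
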