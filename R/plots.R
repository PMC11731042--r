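#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_raster geom_col
#'   geom_point geom_segment scale_fill_viridis_c scale_fill_viridis_d
#'   coord_fixed coord_polar labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a cluster phase map
#'
#' Renders the cluster label image colored by cluster phase (hours), with
#' non-rhythmic clusters greyed out — the standard phase-map view of a
#' slice.
#'
#' @param object a summarized `cluster_map`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot cluster_map
#' @export
autoplot.cluster_map <- function(object, ...) {
  li <- object$label_image
  df <- tibble::tibble(
    row = rep(seq_len(nrow(li)), ncol(li)),
    col = rep(seq_len(ncol(li)), each = nrow(li)),
    cluster = as.vector(li))
  df <- df[!is.na(df$cluster), ]
  if (!is.null(object$summary)) {
    df$phase_h <- object$summary$phase_h[df$cluster]
    df$phase_h[!object$summary$rhythmic[df$cluster]] <- NA
    p <- ggplot(df, aes(.data$col, -.data$row, fill = .data$phase_h)) +
      geom_raster() +
      scale_fill_viridis_c(name = "phase (h)", na.value = "grey70")
  } else {
    p <- ggplot(df, aes(.data$col, -.data$row,
                        fill = factor(.data$cluster))) +
      geom_raster() + scale_fill_viridis_d(name = "cluster")
  }
  p + coord_fixed() + theme_minimal() +
    labs(title = sprintf("Phase map: %s", object$channel),
         x = "column (px)", y = "row (px)")
}

#' Plot cluster mean time series
#'
#' @param cm a `cluster_map`.
#' @return A ggplot of the k normalized cluster mean series.
#' @export
plot_cluster_series <- function(cm) {
  t_h <- (seq_len(ncol(cm$mean_series)) - 1) * cm$dt_h
  df <- tibble::tibble(
    time_h = rep(t_h, each = cm$k),
    cluster = factor(rep(seq_len(cm$k), length(t_h))),
    value = as.vector(cm$mean_series))
  ggplot(df, aes(.data$time_h, .data$value, colour = .data$cluster)) +
    geom_line() + theme_minimal() +
    labs(x = "time (h)", y = "normalized intensity",
         title = sprintf("Cluster series: %s", cm$channel))
}

#' Plot fitted rhythms
#'
#' Observed (points) and FFT-NLLS fitted (line) series, one facet per
#' series.
#'
#' @param object a `rhythm_fit` from [fit_rhythms()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot rhythm_fit
#' @export
autoplot.rhythm_fit <- function(object, ...) {
  cv <- attr(object, "curves")
  if (is.null(cv)) abort("fit has no stored curves")
  ggplot(cv, aes(.data$time_h, .data$observed)) +
    geom_line(alpha = 0.4) +
    geom_line(aes(y = .data$fitted), colour = "firebrick") +
    facet_wrap(~series, scales = "free_y") + theme_minimal() +
    labs(x = "time (h)", y = "intensity")
}

#' Rayleigh-style circular phase plot
#'
#' Plots phases as points on the circle with the mean-resultant vector,
#' whose length encodes synchrony (1 = all phases identical).
#'
#' @param phase_h phases in hours.
#' @param period_h cycle length.
#' @return A ggplot with polar coordinates.
#' @export
plot_rayleigh <- function(phase_h, period_h = 24) {
  th <- hours_to_rad(phase_h, period_h)
  cm <- circ_mean(th)
  df <- tibble::tibble(phase_h = wrap_phase(phase_h, period_h), r = 1)
  p <- ggplot(df, aes(.data$phase_h, .data$r)) +
    geom_point(size = 2, alpha = 0.7) +
    coord_polar(start = 0, direction = 1) +
    ggplot2::scale_x_continuous(limits = c(0, period_h),
                                breaks = seq(0, period_h, by = period_h / 4)) +
    ggplot2::ylim(0, 1.05) + theme_minimal() +
    labs(x = "phase (h)", y = NULL)
  if (!is.na(cm$mean)) {
    p <- p + geom_segment(
      data = tibble::tibble(x = rad_to_hours(cm$mean, period_h), r = cm$R),
      aes(x = .data$x, xend = .data$x, y = 0, yend = .data$r),
      colour = "firebrick", linewidth = 1,
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "in")))
  }
  p
}

#' Plot a phase-distance distribution
#'
#' Histogram of signed phase distances with the wrapped KDE overlaid.
#'
#' @param dist result of [phase_distance_distribution()].
#' @return A ggplot.
#' @export
plot_phase_distances <- function(dist) {
  p <- ggplot(dist$histogram, aes(.data$bin_mid_h, .data$count)) +
    geom_col(fill = "steelblue", alpha = 0.7) + theme_minimal() +
    labs(x = "phase distance from slice mean (h)", y = "cells")
  if (!is.null(dist$kde)) {
    scale <- max(dist$histogram$count) / max(dist$kde$density)
    p <- p + geom_line(data = dist$kde,
                       aes(.data$support, .data$density * scale),
                       colour = "firebrick")
  }
  p
}

#' Plot a circular direction histogram
#'
#' @param dh result of [direction_histogram()].
#' @return A ggplot in polar coordinates.
#' @export
plot_direction_histogram <- function(dh) {
  ggplot(dh$histogram, aes(.data$bin_mid_deg, .data$count)) +
    geom_col(fill = "steelblue", alpha = 0.8, width = diff(dh$histogram$bin_mid_deg[1:2])) +
    coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    theme_minimal() +
    labs(x = "wave direction (deg, ccw from +col)", y = "slices")
}
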