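#' Plot a multiscale dispersion sweep
#'
#' Dispersion index against the number of quadrat cells, with the
#' chi-squared acceptance band; points outside the ribbon reject the
#' homogeneous-Poisson null at the sweep's `alpha`.
#'
#' @param object A `multiscale_dispersion` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot multiscale_dispersion
#' @export
autoplot.multiscale_dispersion <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$statistic),
                       colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$statistic,
                                     colour = .data$verdict), size = 2) +
    ggplot2::labs(x = "number of quadrat cells k", y = "dispersion index",
                  colour = "verdict",
                  title = sprintf(
                    "Multiscale dispersion sweep (n = %d, alpha = %g)",
                    attr(object, "n"), attr(object, "alpha"))) +
    ggplot2::theme_minimal()
}

#' Plot dispersion index against time for a frame-wise report
#'
#' The tabular report drawn the way the assay's figures draw it: one panel
#' per axis, dispersion index over time at a single partition scale, with
#' the chi-squared rejection band shaded.  Cross-axis structure (chemical
#' response) shows as excursions above the band while the long axis should
#' stay inside it.
#'
#' @param object A `dispersion_report` object.
#' @param k Partition scale to display; default the middle of the scales
#'   present.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dispersion_report
#' @export
autoplot.dispersion_report <- function(object, k = NULL, ...) {
  df <- tidy(object)
  ks <- sort(unique(df$k))
  if (is.null(k)) k <- ks[ceiling(length(ks) / 2)]
  if (!k %in% ks) stop(sprintf("k = %d not present in the report", k),
                       call. = FALSE)
  df <- df[df$k == k & !is.na(df$statistic), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$statistic), colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$statistic,
                                     colour = .data$verdict), size = 1.8) +
    ggplot2::facet_wrap(~ .data$axis, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "dispersion index", colour = "verdict",
                  title = sprintf("Dispersion index over time (k = %d)", k)) +
    ggplot2::theme_minimal()
}

#' Snapshot scatter plots of selected frames
#'
#' Organism positions in the unit square for a few frames, faceted by time;
#' the cross axis (`x`, across the fluid bands) is horizontal.
#'
#' @param positions A frame series tibble (`frame`, `time`, `x`, `y`).
#' @param times Times (seconds) of the frames to show; each is matched to
#'   the nearest available frame.  Default: first, middle and last frame.
#' @param band Optional `c(a, b)` to shade the loaded central band.
#' @return A ggplot object.
#' @export
plot_frames <- function(positions, times = NULL, band = NULL) {
  stopifnot(is.data.frame(positions))
  avail <- sort(unique(positions$time))
  if (is.null(times)) {
    times <- avail[unique(c(1, ceiling(length(avail) / 2), length(avail)))]
  } else {
    times <- vapply(times, function(t) avail[which.min(abs(avail - t))],
                    numeric(1))
  }
  df <- positions[positions$time %in% times &
                    !(is.na(positions$x) & is.na(positions$y)), ]
  df$label <- factor(sprintf("t = %g s", df$time),
                     levels = sprintf("t = %g s", sort(unique(df$time))))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(band)) {
    p <- p + ggplot2::annotate("rect", xmin = band[1], xmax = band[2],
                               ymin = 0, ymax = 1, fill = "steelblue",
                               alpha = 0.15)
  }
  p + ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::facet_wrap(~ .data$label) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "cross axis", y = "long axis") +
    ggplot2::theme_minimal()
}
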