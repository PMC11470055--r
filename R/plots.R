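#' Plot an MSD curve
#'
#' @param object An [compute_msd()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msd_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_s, y = .data$msd)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (s)", y = expression(MSD ~ (mu * m^2))) +
    ggplot2::theme_minimal()
}

#' Plot a FRAP fit over its trace
#'
#' @param object A `frap_fit` from [fit_frap_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frap_fit <- function(object, ...) {
  d <- tibble(t = object$t, F = object$F)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$F)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "time from bleach (s)", y = "normalized fluorescence") +
    ggplot2::theme_minimal()
  if (object$converged && !object$degenerate) {
    grid <- tibble(t = seq(0, max(object$t), length.out = 200))
    grid$F <- .frap_model(grid$t, object$F0, object$p, object$tauf,
                          object$q, object$taus)
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}

#' Plot a population-average FRAP recovery curve
#'
#' @param object A [population_recovery()] result.
#' @param ... Unused.
#' @return A ggplot with the mean curve and an s.e.m. ribbon.
#' @export
autoplot.frap_population <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$t, y = .data$mean_F)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_F - .data$sem_F,
                                      ymax = .data$mean_F + .data$sem_F),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from bleach (s)",
                  y = "normalized fluorescence (mean ± sem)") +
    ggplot2::theme_minimal()
}

#' Plot the nanocolumn centroid-distance distribution
#'
#' @param object A [pair_nanocolumns()] result.
#' @param bin_width Histogram bin width in nm.
#' @param ... Unused.
#' @return A ggplot of the relative-frequency histogram.
#' @export
autoplot.nanocolumn_pairing <- function(object, bin_width = 20, ...) {
  h <- pairing_histogram(object, bin_width = bin_width)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid, y = .data$rel_freq)) +
    ggplot2::geom_col(width = bin_width * 0.9) +
    ggplot2::labs(x = "centroid-to-centroid distance (nm)",
                  y = "relative frequency") +
    ggplot2::theme_minimal()
}

#' Plot trajectories colored by motion class
#'
#' @param tracks Track tibble (`track_id`, `x_um`, `y_um`).
#' @param reports Optional [classify_tracks()] table to color by class.
#' @return A ggplot.
#' @export
plot_tracks <- function(tracks, reports = NULL) {
  d <- tracks
  if (!is.null(reports)) {
    d <- left_join(d, reports[, c("track_id", "motion_class")], by = "track_id")
  } else {
    d$motion_class <- "track"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                  group = .data$track_id,
                                  colour = .data$motion_class)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a pH-switch trace with its phase structure
#'
#' @param traces Trace tibble from [simulate_ph_traces()] or a matching
#'   CSV.
#' @return A ggplot faceted by object.
#' @export
plot_ph_trace <- function(traces) {
  if (inherits(traces, "ph_sim")) traces <- traces$traces
  ggplot2::ggplot(traces, ggplot2::aes(x = .data$frame, y = .data$intensity,
                                       colour = .data$phase)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$object_id), colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~object_id) +
    ggplot2::labs(x = "frame", y = "intensity (a.u.)", colour = "phase") +
    ggplot2::theme_minimal()
}
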