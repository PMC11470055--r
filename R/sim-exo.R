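#' Construct ground truth for exocytosis movies
#'
#' One row per planted exocytic event: a diffraction-limited spot appearing
#' at `onset_frame` whose amplitude decays exponentially with time constant
#' `decay_tau` (seconds), as cargo disperses from the fusion site.
#'
#' @param x_px,y_px Event positions in pixels (1-based, x = column,
#'   y = row).
#' @param onset_frame Frame at which each event appears.
#' @param amplitude Peak amplitude above baseline, a.u.
#' @param decay_tau Decay time constant in seconds.
#' @param noise_sd Gaussian read noise per pixel, a.u.
#' @return Tibble of class `exo_truth` with attribute `noise_sd`.
#' @export
exo_truth <- function(x_px = numeric(), y_px = numeric(),
                      onset_frame = integer(), amplitude = numeric(),
                      decay_tau = numeric(), noise_sd = 1) {
  if (any(amplitude <= 0)) abort("`amplitude` must be positive")
  out <- tibble(
    event_id = seq_along(x_px),
    x_px = x_px, y_px = y_px,
    onset_frame = as.integer(onset_frame),
    amplitude = amplitude,
    decay_tau = rep_len(decay_tau, length(x_px))
  )
  attr(out, "noise_sd") <- noise_sd
  class(out) <- c("exo_truth", class(out))
  out
}

#' Simulate a post-bleach movie with planted exocytic events
#'
#' Renders each event as a 2D Gaussian spot (sd `spot_sigma_px`) appearing
#' at its onset frame with amplitude decaying as `exp(-(t - t_onset) /
#' decay_tau)`, on a flat baseline with additive Gaussian read noise,
#' clipped at zero. The movie is a numeric array indexed
#' `[row, column, frame]`.
#'
#' @param config A [sim_config()] (seed only).
#' @param truth An [exo_truth()] table.
#' @param frame_count Number of frames.
#' @param width,height Movie size in pixels.
#' @param dt Seconds per frame (default 2 s, a 0.5 Hz acquisition).
#' @param spot_sigma_px Gaussian spot sd in pixels.
#' @param baseline Constant baseline level, a.u.
#' @return List of class `exo_sim`: `movie` (array height x width x
#'   frames), `dt`, and `truth`.
#' @export
#' @examples
#' tr <- exo_truth(x_px = 30, y_px = 30, onset_frame = 20,
#'                 amplitude = 50, decay_tau = 4, noise_sd = 2)
#' sim <- simulate_exo_movie(sim_config(1), tr, frame_count = 60,
#'                           width = 64, height = 64)
#' dim(sim$movie)
simulate_exo_movie <- function(config, truth, frame_count = 100,
                               width = 128, height = 128, dt = 2,
                               spot_sigma_px = 2, baseline = 100) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "exo_truth"))
  if (nrow(truth) > 0) {
    if (any(truth$onset_frame < 1 | truth$onset_frame > frame_count)) {
      abort("event `onset_frame` must lie within the movie")
    }
    if (any(truth$x_px < 1 | truth$x_px > width |
              truth$y_px < 1 | truth$y_px > height)) {
      abort("event position outside the field of view")
    }
  }
  set_sim_seed(config, offset = 505L)
  noise_sd <- attr(truth, "noise_sd") %||% 0

  movie <- array(baseline, dim = c(height, width, frame_count))
  half <- ceiling(4 * spot_sigma_px)
  for (i in seq_len(nrow(truth))) {
    ev <- truth[i, ]
    rows <- max(1, round(ev$y_px) - half):min(height, round(ev$y_px) + half)
    cols <- max(1, round(ev$x_px) - half):min(width, round(ev$x_px) + half)
    g <- outer(
      exp(-(rows - ev$y_px)^2 / (2 * spot_sigma_px^2)),
      exp(-(cols - ev$x_px)^2 / (2 * spot_sigma_px^2))
    )
    for (f in ev$onset_frame:frame_count) {
      amp <- ev$amplitude * exp(-(f - ev$onset_frame) * dt / ev$decay_tau)
      movie[rows, cols, f] <- movie[rows, cols, f] + amp * g
    }
  }
  if (noise_sd > 0) {
    movie <- movie + array(rnorm(length(movie), sd = noise_sd), dim = dim(movie))
  }
  movie[movie < 0] <- 0
  structure(list(movie = movie, dt = dt, truth = truth), class = "exo_sim")
}
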