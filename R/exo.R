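#' Exocytosis event-detection parameters
#'
#' @param k_sigma Detection threshold in units of the smoothed-image noise
#'   sd (default 5).
#' @param spot_radius_px Disk radius (pixels) of the matched averaging
#'   filter and of the spatial merge window.
#' @param min_separation_frames Candidates closer than this in time and
#'   within the spatial merge window are the same event.
#' @param baseline_window_frames Leading frames used to estimate the noise
#'   sd.
#' @return Object of class `exo_params`.
#' @export
exo_params <- function(k_sigma = 5, spot_radius_px = 2,
                       min_separation_frames = 2,
                       baseline_window_frames = 10) {
  check_positive_scalar(k_sigma, "k_sigma")
  check_positive_scalar(spot_radius_px, "spot_radius_px")
  structure(
    list(k_sigma = k_sigma, spot_radius_px = spot_radius_px,
         min_separation_frames = min_separation_frames,
         baseline_window_frames = baseline_window_frames),
    class = "exo_params"
  )
}

# disk mean filter applied framewise (circular convolution at edges)
.disk_smooth <- function(movie, radius_px) {
  brush <- EBImage::makeBrush(2 * radius_px + 1, shape = "disc")
  brush <- brush / sum(brush)
  out <- movie
  for (f in seq_len(dim(movie)[3])) {
    out[, , f] <- as.matrix(EBImage::filter2(EBImage::Image(movie[, , f]), brush))
  }
  out
}

#' Detect exocytic appearance events in a post-bleach movie
#'
#' Works on the disk-averaged movie (radius `spot_radius_px`). The noise
#' scale `sigma` of a one-frame intensity jump of the smoothed signal is
#' estimated from frame-to-frame differences inside the leading baseline
#' window. A candidate is a pixel whose smoothed intensity rises more
#' than `k_sigma * sigma` above its local pre-event baseline (the mean of
#' the up-to-three preceding frames) within one frame and stays more than
#' `0.75 * k_sigma * sigma` above it in the following frame (the
#' persistence check suppresses single-frame noise excursions).
#' Candidates are merged when they fall within `3 * spot_radius_px`
#' pixels and `min_separation_frames` frames of a stronger one.
#'
#' @param movie Numeric array `[row, column, frame]` (e.g. from
#'   [simulate_exo_movie()] or [read_movie_tiff()]).
#' @param params An [exo_params()].
#' @param dt Seconds per frame (propagated to event traces).
#' @return Tibble of class `exo_events`: `event_id`, `x_px`, `y_px`,
#'   `onset_frame`, `jump` (smoothed intensity step), and a list-column
#'   `trace` with the disk-averaged ROI trace (`frame`, `t`, `intensity`,
#'   baseline-subtracted) from onset onward.
#' @export
detect_events <- function(movie, params = exo_params(), dt = 2) {
  stopifnot(is.array(movie), length(dim(movie)) == 3)
  n_frames <- dim(movie)[3]
  if (n_frames <= params$baseline_window_frames) {
    abort("movie shorter than the baseline window")
  }
  sm <- .disk_smooth(movie, params$spot_radius_px)
  base <- sm[, , seq_len(params$baseline_window_frames)]
  diffs <- base[, , -1, drop = FALSE] - base[, , -dim(base)[3], drop = FALSE]
  # noise scale of a one-frame jump of the smoothed signal
  sigma <- sd(diffs)
  if (sigma == 0) sigma <- .Machine$double.eps

  thr <- params$k_sigma * sigma
  cands <- list()
  for (f in 2:(n_frames - 1)) {
    # local pre-event baseline: mean of up to three preceding frames, so a
    # single downward noise excursion cannot fake a jump
    pre_idx <- max(1, f - 3):(f - 1)
    pre <- sm[, , pre_idx[1]]
    for (pi in pre_idx[-1]) pre <- pre + sm[, , pi]
    pre <- pre / length(pre_idx)
    jump <- sm[, , f] - pre
    persist <- sm[, , f + 1] - pre
    hit <- which(jump > thr & persist > 0.75 * thr, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      cands[[length(cands) + 1]] <- tibble(
        y_px = hit[, 1], x_px = hit[, 2], onset_frame = f,
        jump = jump[hit]
      )
    }
  }
  empty <- tibble(event_id = integer(), x_px = integer(), y_px = integer(),
                  onset_frame = integer(), jump = double(), trace = list())
  if (length(cands) == 0) {
    class(empty) <- c("exo_events", class(empty))
    return(empty)
  }
  cands <- bind_rows(cands)
  cands <- cands[order(-cands$jump), ]
  merge_px <- 3 * params$spot_radius_px
  kept <- cands[0, ]
  for (i in seq_len(nrow(cands))) {
    ci <- cands[i, ]
    dup <- nrow(kept) > 0 &&
      any(abs(kept$x_px - ci$x_px) <= merge_px &
            abs(kept$y_px - ci$y_px) <= merge_px &
            abs(kept$onset_frame - ci$onset_frame) <= params$min_separation_frames)
    if (!dup) kept <- bind_rows(kept, ci)
  }
  kept <- kept[order(kept$onset_frame, kept$x_px), ]
  kept$event_id <- seq_len(nrow(kept))
  kept$trace <- purrr::map(seq_len(nrow(kept)), function(i) {
    tr <- sm[kept$y_px[i], kept$x_px[i], ]
    pre <- mean(tr[max(1, kept$onset_frame[i] - params$baseline_window_frames):
                     (kept$onset_frame[i] - 1)])
    fr <- kept$onset_frame[i]:n_frames
    tibble(frame = fr, t = (fr - kept$onset_frame[i]) * dt,
           intensity = tr[fr] - pre)
  })
  out <- kept[, c("event_id", "x_px", "y_px", "onset_frame", "jump", "trace")]
  class(out) <- c("exo_events", class(out))
  out
}

#' Fit a single-exponential decay to an event trace
#'
#' Least squares of `A * exp(-t / tau) + c` from the trace peak onward.
#' The single-exponential form with offset is the default decay model; a
#' constant trace cannot be fitted and returns `fit_ok = FALSE`.
#'
#' @param trace Tibble with `t` (seconds) and `intensity`, starting at the
#'   event onset (as produced by [detect_events()]).
#' @return Object of class `exo_decay_fit`: `amplitude`, `decay_tau` (s),
#'   `offset`, `fit_ok`, `rss`, `n`.
#' @export
#' @examples
#' t <- seq(0, 20, by = 0.5)
#' fit_event_decay(tibble::tibble(t = t, intensity = 100 * exp(-t / 2)))
fit_event_decay <- function(trace) {
  check_columns(trace, c("t", "intensity"), "event trace")
  peak <- which.max(trace$intensity)
  d <- trace[peak:nrow(trace), ]
  d$t <- d$t - d$t[1]
  out <- list(amplitude = NA_real_, decay_tau = NA_real_, offset = NA_real_,
              fit_ok = FALSE, rss = NA_real_, n = nrow(d))
  class(out) <- "exo_decay_fit"
  if (nrow(d) < 4 || sd(d$intensity) < 1e-12) return(out)
  span <- max(d$t)
  fit <- nls_lm_fit(
    par = c(A = max(d$intensity) - min(d$intensity),
            tau = span / 3, c0 = min(d$intensity)),
    resid_fn = function(p) {
      d$intensity - (p[["A"]] * exp(-d$t / p[["tau"]]) + p[["c0"]])
    },
    lower = c(A = 1e-9, tau = 1e-6, c0 = -Inf),
    maxiter = 200
  )
  if (is.null(fit)) return(out)
  p <- fit$par
  out$amplitude <- unname(p["A"])
  out$decay_tau <- unname(p["tau"])
  out$offset <- unname(p["c0"])
  out$fit_ok <- TRUE
  out$rss <- fit$rss
  out
}

#' @export
print.exo_decay_fit <- function(x, ...) {
  cat("<exo_decay_fit>")
  if (x$fit_ok) {
    cat(sprintf(" A = %.4g, tau = %.4g s, offset = %.4g\n",
                x$amplitude, x$decay_tau, x$offset))
  } else cat(" fit failed\n")
  invisible(x)
}

#' Exocytosis event frequency
#'
#' @param events An [detect_events()] table, or an event count.
#' @param cell_area_um2 Imaged cell area in um^2.
#' @param duration_s Recording duration in seconds.
#' @return One-row tibble: `n_events`, `cell_area_um2`, `duration_s`,
#'   `frequency` in events per um^2 per second.
#' @export
#' @examples
#' event_frequency(6, cell_area_um2 = 100, duration_s = 60)$frequency # 1e-3
event_frequency <- function(events, cell_area_um2, duration_s) {
  check_positive_scalar(cell_area_um2, "cell_area_um2")
  check_positive_scalar(duration_s, "duration_s")
  n <- if (is.numeric(events) && length(events) == 1) events else nrow(events)
  tibble(n_events = n, cell_area_um2 = cell_area_um2, duration_s = duration_s,
         frequency = n / (cell_area_um2 * duration_s))
}
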