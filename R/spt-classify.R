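# point-in-mask lookup: trajectory coordinates (um) to 0-based pixel by
# floor after scaling, then 1-based matrix indexing; outside raster = outside
point_in_mask <- function(x_um, y_um, masks) {
  stopifnot(inherits(masks, "synapse_mask"))
  px <- masks$pixel_size_um
  col <- floor(x_um / px) + 1L
  row <- floor(y_um / px) + 1L
  inside <- rep(FALSE, length(x_um))
  ok <- row >= 1 & row <= nrow(masks$mask) & col >= 1 & col <= ncol(masks$mask)
  inside[ok] <- masks$mask[cbind(row[ok], col[ok])] > 0
  inside
}

#' Sort a trajectory as synaptic or extra-synaptic and measure dwell time
#'
#' A trajectory is synaptic when it spends more than
#' `synaptic_fraction_cut` (default 50%) of its duration inside a
#' synapse-marker-positive area. Dwell time is computed for every
#' trajectory that crosses a synapse (at least one frame inside) as the
#' inside-frame count times the frame interval, both per entry-to-exit
#' visit and as a per-track total. Coordinates falling outside the mask
#' raster are treated as outside and counted in `n_outside_raster`.
#'
#' @param traj Single-track data frame with `frame`, `x_um`, `y_um`.
#' @param masks A [synapse_mask()] in the same coordinate frame.
#' @param cfg An [spt_config()].
#' @return List: `is_synaptic`, `inside_fraction`, `dwell_time_s` (total;
#'   `NA` if the track never enters a synapse), `visits` (tibble with one
#'   row per entry-to-exit visit: `visit`, `n_frames`, `dwell_s`), and
#'   `n_outside_raster`.
#' @export
#' @examples
#' m <- synapse_mask(c(2, 2), centers = cbind(1, 1), radius_um = 1)
#' traj <- data.frame(frame = 1:25, x_um = rep(1, 25), y_um = rep(1, 25))
#' assign_synaptic(traj, m, spt_config())$dwell_time_s # 0.5
assign_synaptic <- function(traj, masks, cfg = spt_config()) {
  check_columns(traj, c("frame", "x_um", "y_um"), "trajectory")
  px <- masks$pixel_size_um
  col <- floor(traj$x_um / px) + 1L
  row <- floor(traj$y_um / px) + 1L
  off_raster <- !(row >= 1 & row <= nrow(masks$mask) &
                    col >= 1 & col <= ncol(masks$mask))
  inside <- point_in_mask(traj$x_um, traj$y_um, masks)
  frac <- mean(inside)
  runs <- rle(inside)
  visit_frames <- runs$lengths[runs$values]
  visits <- tibble(
    visit = seq_along(visit_frames),
    n_frames = as.integer(visit_frames),
    dwell_s = visit_frames * cfg$dt
  )
  list(
    is_synaptic = frac > cfg$synaptic_fraction_cut,
    inside_fraction = frac,
    dwell_time_s = if (any(inside)) sum(inside) * cfg$dt else NA_real_,
    visits = visits,
    n_outside_raster = sum(off_raster)
  )
}

# classify one trajectory given its MSD curve
.classify_one <- function(traj, cfg) {
  n <- nrow(traj)
  max_lag <- min(cfg$conf_fit_lags, n - 1)
  msd <- compute_msd(traj, max_lag = max_lag, dt = cfg$dt)
  lin <- fit_linear_diffusion(msd, cfg)
  D <- lin$D
  if (D < cfg$D_threshold) {
    return(list(D = D, motion_class = "immobile", r_conf = NA_real_,
                tau = NA_real_, D_diff = NA_real_, fit_flag = "ok"))
  }
  cf <- tryCatch(fit_confinement(msd, cfg), error = function(e) NULL)
  if (is.null(cf) || !cf$converged) {
    return(list(D = D, motion_class = "diffusive", r_conf = NA_real_,
                tau = NA_real_, D_diff = D, fit_flag = "confinement_fit_failed"))
  }
  # tie at the threshold counts as confined (closed on the confined side)
  if (cf$tau <= cfg$tau_threshold) {
    list(D = D, motion_class = "confined", r_conf = cf$r_conf,
         tau = cf$tau, D_diff = NA_real_, fit_flag = "ok")
  } else {
    list(D = D, motion_class = "diffusive", r_conf = NA_real_,
         tau = cf$tau, D_diff = D, fit_flag = "ok")
  }
}

#' Classify trajectories as immobile, confined, or diffusive
#'
#' Per track: the diffusion coefficient is estimated from the initial MSD
#' slope ([fit_linear_diffusion()]); tracks with `D` below the immobility
#' threshold are immobile; the remaining MSDs are fitted with the
#' confinement model ([fit_confinement()]) and split into confined
#' (fitted `tau` at or below `tau_threshold`) and diffusive. For diffusive
#' tracks the reported `D_diff` comes from the same initial-slope linear
#' fit. Tracks shorter than `min_points` are dropped before analysis.
#' When `masks` is supplied, each report also carries the synaptic status
#' and dwell time from [assign_synaptic()].
#'
#' @param tracks Tibble with `track_id`, `frame`, `x_um`, `y_um` (several
#'   tracks in long format).
#' @param cfg An [spt_config()].
#' @param masks Optional [synapse_mask()].
#' @return Tibble of class `motion_report`, one row per analyzed track:
#'   `track_id`, `n_points`, `D`, `motion_class`, `r_conf`, `tau`,
#'   `D_diff`, `fit_flag`, and (with masks) `is_synaptic`,
#'   `inside_fraction`, `dwell_time_s`.
#' @export
#' @examples
#' sim <- simulate_trajectories(sim_config(1),
#'                              n_per_class = c(brownian = 5, immobile = 5))
#' classify_tracks(sim$tracks, spt_config())
classify_tracks <- function(tracks, cfg = spt_config(), masks = NULL) {
  check_columns(tracks, c("track_id", "frame", "x_um", "y_um"), "track table")
  split_tracks <- split(tracks, tracks$track_id)
  keep <- vapply(split_tracks, nrow, integer(1)) >= cfg$min_points
  split_tracks <- split_tracks[keep]
  if (length(split_tracks) == 0) {
    abort(sprintf("no track reaches the minimum length of %d points", cfg$min_points))
  }
  rows <- purrr::map(split_tracks, function(tr) {
    tr <- tr[order(tr$frame), ]
    res <- .classify_one(tr, cfg)
    row <- tibble(
      track_id = tr$track_id[1], n_points = nrow(tr),
      D = res$D, motion_class = res$motion_class,
      r_conf = res$r_conf, tau = res$tau, D_diff = res$D_diff,
      fit_flag = res$fit_flag
    )
    if (!is.null(masks)) {
      syn <- assign_synaptic(tr, masks, cfg)
      row$is_synaptic <- syn$is_synaptic
      row$inside_fraction <- syn$inside_fraction
      row$dwell_time_s <- syn$dwell_time_s
    }
    row
  })
  out <- bind_rows(rows)
  class(out) <- c("motion_report", class(out))
  out
}

#' Summarize a population of motion reports
#'
#' Computes the fractions of immobile, confined, and diffusive
#' trajectories (summing to one), the percentage of non-synaptic tracks
#' and the mean synaptic dwell time (over tracks that cross a synapse)
#' when synaptic sorting was performed, and the diffusive-track diffusion
#' coefficients.
#'
#' @param reports A [classify_tracks()] tibble.
#' @param by Optional name of a grouping column in `reports` (e.g. a cell
#'   id) for per-cell aggregation.
#' @return Tibble with one row per group: `n_tracks`, `frac_immobile`,
#'   `frac_confined`, `frac_diffusive`, `pct_non_synaptic`,
#'   `mean_dwell_s` (both `NA` without synaptic data), and a list-column
#'   `D_diff` holding the diffusive-track coefficients.
#' @export
summarize_population <- function(reports, by = NULL) {
  if (nrow(reports) == 0) abort("`reports` is empty")
  grouped <- if (!is.null(by)) group_by(reports, .data[[by]]) else reports
  out <- summarise(
    grouped,
    n_tracks = n(),
    frac_immobile = mean(.data$motion_class == "immobile"),
    frac_confined = mean(.data$motion_class == "confined"),
    frac_diffusive = mean(.data$motion_class == "diffusive"),
    pct_non_synaptic = if ("is_synaptic" %in% names(reports)) {
      100 * mean(!.data$is_synaptic)
    } else NA_real_,
    mean_dwell_s = if ("dwell_time_s" %in% names(reports)) {
      mean(.data$dwell_time_s, na.rm = TRUE)
    } else NA_real_,
    D_diff = list(.data$D_diff[.data$motion_class == "diffusive"]),
    .groups = "drop"
  )
  as_tibble(out)
}
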