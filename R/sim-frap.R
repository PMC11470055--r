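#' Construct a table of FRAP ground-truth parameters
#'
#' One row per bleached region. The recovery model is the double
#' exponential `F(t) = F0 + p (1 - exp(-t/tauf)) + q (1 - exp(-t/taus))`
#' in units normalized to the pre-bleach level, where `p` and `q` are the
#' fast- and slow-pool fractions and `tauf < taus` their time constants.
#'
#' @param n Number of regions.
#' @param region_class `"spine"` or `"shaft"` (recycled).
#' @param F0,p,q Model fractions (recycled); `F0 + p + q` must be in [0, 1].
#' @param tauf,taus Fast and slow time constants in seconds; `tauf < taus`.
#' @param bleach_depth Fraction of the pre-bleach signal removed by the
#'   bleach pulse (1 = complete bleach).
#' @param noise_sd Gaussian intensity noise, in raw intensity units.
#' @return Tibble of class `frap_truth`.
#' @export
frap_truth <- function(n = 1, region_class = "spine",
                       F0 = 0, p = 0.5, q = 0.3,
                       tauf = 5, taus = 120,
                       bleach_depth = 0.9, noise_sd = 0) {
  out <- tibble(
    region_id = seq_len(n),
    region_class = rep_len(region_class, n),
    F0_true = rep_len(F0, n),
    p_true = rep_len(p, n),
    q_true = rep_len(q, n),
    tauf_true = rep_len(tauf, n),
    taus_true = rep_len(taus, n),
    bleach_depth_true = rep_len(bleach_depth, n),
    noise_sd = rep_len(noise_sd, n)
  )
  if (any(out$tauf_true >= out$taus_true)) {
    abort("`tauf` must be strictly smaller than `taus` for every region")
  }
  tot <- out$F0_true + out$p_true + out$q_true
  if (any(tot < 0 | tot > 1) || any(out$F0_true < 0 | out$p_true < 0 | out$q_true < 0)) {
    abort("F0, p, q must be non-negative with F0 + p + q in [0, 1]")
  }
  class(out) <- c("frap_truth", class(out))
  out
}

#' Simulate raw FRAP traces from the double-exponential recovery model
#'
#' Produces raw (un-normalized) region traces with ten pre-bleach frames at
#' plateau, a bleach step to `1 - bleach_depth` of the plateau, and
#' post-bleach recovery following the double-exponential model of
#' [frap_truth()]. All photon signal (bleached region and reference region)
#' decays at `acquisition_bleach_rate` per frame to emulate acquisition
#' photobleaching; an unbleached reference-region trace and a constant
#' background trace are included so the analysis side can invert both
#' effects.
#'
#' @param config A [sim_config()] (its seed drives the noise).
#' @param truths A [frap_truth()] table.
#' @param n_post Number of post-bleach frames (default 150).
#' @param dt Seconds per frame (default 1, a 1 Hz acquisition).
#' @param acquisition_bleach_rate Per-frame fraction of signal lost to
#'   acquisition (default 0).
#' @param pre_level Pre-bleach ROI signal above background, a.u.
#' @param background Constant background level, a.u.
#' @return List of class `frap_sim`: `traces` (tibble with `region_id`,
#'   `region_class`, `frame`, `time_s`, `roi_intensity`, `bg_intensity`,
#'   `ref_intensity`), `bleach_frame` (first post-bleach frame index), and
#'   `truth`.
#' @export
#' @examples
#' sim <- simulate_frap_traces(sim_config(1), frap_truth(2, noise_sd = 5))
#' head(sim$traces)
simulate_frap_traces <- function(config, truths,
                                 n_post = 150, dt = 1,
                                 acquisition_bleach_rate = 0,
                                 pre_level = 1000, background = 100) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("tauf_true", "taus_true") %in% names(truths))) {
    abort("`truths` must be a frap_truth() table")
  }
  if (any(truths$tauf_true >= truths$taus_true)) {
    abort("`tauf` must be strictly smaller than `taus` for every region")
  }
  if (acquisition_bleach_rate < 0 || acquisition_bleach_rate >= 1) {
    abort("`acquisition_bleach_rate` must be in [0, 1)")
  }
  set_sim_seed(config, offset = 202L)

  n_pre <- 10L
  bleach_frame <- n_pre + 1L # first post-bleach frame
  n_frames <- n_pre + n_post
  frames <- seq_len(n_frames)
  decay <- (1 - acquisition_bleach_rate)^(frames - 1)

  traces <- purrr::pmap(truths, function(region_id, region_class, F0_true,
                                         p_true, q_true, tauf_true, taus_true,
                                         bleach_depth_true, noise_sd, ...) {
    t_post <- (frames - bleach_frame) * dt
    f <- F0_true +
      p_true * (1 - exp(-pmax(t_post, 0) / tauf_true)) +
      q_true * (1 - exp(-pmax(t_post, 0) / taus_true))
    level <- ifelse(frames < bleach_frame, 1,
                    (1 - bleach_depth_true) + bleach_depth_true * f)
    roi <- background + pre_level * decay * level
    if (noise_sd > 0) roi <- roi + rnorm(n_frames, sd = noise_sd)
    tibble(
      region_id = region_id, region_class = region_class,
      frame = frames, time_s = (frames - bleach_frame) * dt,
      roi_intensity = roi,
      bg_intensity = background,
      ref_intensity = background + pre_level * decay
    )
  })

  structure(
    list(traces = bind_rows(traces), bleach_frame = bleach_frame,
         dt = dt, truth = truths),
    class = "frap_sim"
  )
}
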