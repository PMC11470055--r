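#' Construct ground truth for pH-switch traces
#'
#' One row per imaged object (a spine or a stretch of dendritic shaft).
#' `surface_fraction` is the fraction of the object's total fluorescent
#' pool residing at the plasma membrane; the remainder is intracellular.
#'
#' @param n Number of objects.
#' @param compartment `"spine"` or `"shaft"` (recycled).
#' @param total Total pool intensity per object, a.u. (recycled).
#' @param surface_fraction Fraction in [0, 1] at the surface (recycled).
#' @return Tibble of class `ph_truth` with the planted per-object pools and
#'   the implied spine share of the intracellular pool as attribute
#'   `spine_share_pct`.
#' @export
ph_truth <- function(n = 1, compartment = "spine", total = 1000,
                     surface_fraction = 0.8) {
  sf <- rep_len(surface_fraction, n)
  if (any(sf < 0 | sf > 1)) abort("`surface_fraction` must be in [0, 1]")
  out <- tibble(
    object_id = seq_len(n),
    compartment = rep_len(compartment, n),
    total_true = rep_len(total, n),
    surface_fraction_true = sf,
    surface_true = rep_len(total, n) * sf,
    intracellular_true = rep_len(total, n) * (1 - sf)
  )
  intra <- out$intracellular_true
  attr(out, "spine_share_pct") <-
    if (sum(intra) > 0) 100 * sum(intra[out$compartment == "spine"]) / sum(intra) else NA_real_
  class(out) <- c("ph_truth", class(out))
  out
}

#' Simulate five-phase pH-switch traces
#'
#' Emulates the perfusion protocol used to separate surface from
#' intracellular pools of a pHluorin-tagged protein: (1) baseline at pH
#' 7.4, (2) pH 5.5 quenching surface fluorescence, (3) baseline, (4)
#' NH4Cl de-acidifying intracellular vesicles and revealing the total
#' pool, (5) baseline. Phase plateau levels per object are
#' `baseline = surface`, `pH5.5 = surface * (1 - quench_efficiency)`,
#' `NH4Cl = total`. The first `transition_frames` frames of each phase
#' after the first interpolate linearly between plateau levels, emulating
#' solution exchange; the analysis side excludes them from phase means.
#'
#' @param config A [sim_config()].
#' @param truths A [ph_truth()] table.
#' @param quench_efficiency Fraction of surface fluorescence quenched at
#'   pH 5.5 (default 0.9, i.e. ~90%).
#' @param phase_lengths Integer length-5, frames per phase (each >= 3).
#' @param noise_sd Gaussian intensity noise, a.u.
#' @param transition_frames Frames of linear mixing at each switch.
#' @return List of class `ph_sim`: `traces` (tibble `object_id`,
#'   `compartment`, `frame`, `intensity`, `phase`), `truth`, and the
#'   protocol parameters.
#' @export
#' @examples
#' sim <- simulate_ph_traces(sim_config(1), ph_truth(1, surface_fraction = 0.8))
#' table(sim$traces$phase)
simulate_ph_traces <- function(config, truths,
                               quench_efficiency = 0.9,
                               phase_lengths = c(10, 10, 10, 10, 10),
                               noise_sd = 0,
                               transition_frames = 2) {
  stopifnot(inherits(config, "sim_config"))
  if (length(phase_lengths) != 5) {
    abort("`phase_lengths` must give exactly 5 phases (baseline1, pH5.5, baseline2, NH4Cl, baseline3)")
  }
  if (any(phase_lengths < 3)) abort("every phase needs at least 3 frames")
  if (quench_efficiency < 0 || quench_efficiency > 1) {
    abort("`quench_efficiency` must be in [0, 1]")
  }
  set_sim_seed(config, offset = 303L)

  phases <- ph_phases()
  phase_vec <- rep(phases, times = phase_lengths)
  n_frames <- length(phase_vec)

  traces <- purrr::pmap(truths, function(object_id, compartment, total_true,
                                         surface_fraction_true, surface_true,
                                         intracellular_true, ...) {
    levels <- c(
      baseline1 = surface_true,
      pH5.5 = surface_true * (1 - quench_efficiency),
      baseline2 = surface_true,
      NH4Cl = total_true,
      baseline3 = surface_true
    )
    y <- unname(levels[phase_vec])
    # linear mixing across each solution switch
    if (transition_frames > 0) {
      bounds <- cumsum(phase_lengths)
      for (b in head(bounds, -1)) {
        prev <- y[b]
        for (k in seq_len(min(transition_frames, n_frames - b))) {
          w <- k / (transition_frames + 1)
          y[b + k] <- (1 - w) * prev + w * unname(levels[phase_vec[b + k]])
        }
      }
    }
    if (noise_sd > 0) y <- y + rnorm(n_frames, sd = noise_sd)
    tibble(object_id = object_id, compartment = compartment,
           frame = seq_len(n_frames), intensity = y, phase = phase_vec)
  })

  structure(
    list(traces = bind_rows(traces), truth = truths,
         quench_efficiency = quench_efficiency,
         phase_lengths = phase_lengths,
         transition_frames = transition_frames),
    class = "ph_sim"
  )
}

# canonical phase order of the pH-switch protocol
ph_phases <- function() c("baseline1", "pH5.5", "baseline2", "NH4Cl", "baseline3")
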