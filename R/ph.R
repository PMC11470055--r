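#' Estimate surface and intracellular pools from a pH-switch trace
#'
#' The surface pool is the mean fluorescence over the three baseline
#' phases (pH 7.4), the total pool is the mean under NH4Cl (intracellular
#' vesicles de-acidified, all molecules fluorescent), and the
#' intracellular pool is their difference. The quench percentage compares
#' the pH 5.5 phase to baseline. The first `transition_frames` frames of
#' each phase are excluded from the phase means to avoid mixed-solution
#' frames. Input traces must be background-subtracted.
#'
#' @param traces Tibble with `object_id`, `frame`, `intensity`, `phase`
#'   (phases `baseline1`, `pH5.5`, `baseline2`, `NH4Cl`, `baseline3`; a
#'   `compartment` column is carried through). Accepts a
#'   [simulate_ph_traces()] result directly.
#' @param transition_frames Frames dropped at the start of every phase
#'   after the first (default 2; set 0 to use all frames).
#' @param noise_tol Tolerance for `surface > total`: estimates where the
#'   surface exceeds the total by more than `noise_tol * total` are
#'   flagged.
#' @return Tibble of class `pool_estimate`, one row per object: `total`,
#'   `surface`, `intracellular`, `intracellular_pct`, `quench_pct`,
#'   `flag` (`ok`, `nonpositive_total`, or `surface_exceeds_total`).
#'   `intracellular = total - surface` exactly.
#' @export
#' @examples
#' sim <- simulate_ph_traces(sim_config(1), ph_truth(1, surface_fraction = 0.8))
#' estimate_pools(sim$traces)$intracellular_pct # 20
estimate_pools <- function(traces, transition_frames = 2, noise_tol = 0.05) {
  if (inherits(traces, "ph_sim")) {
    transition_frames <- max(transition_frames, traces$transition_frames)
    traces <- traces$traces
  }
  check_columns(traces, c("object_id", "frame", "intensity", "phase"), "pH traces")
  phases <- ph_phases()
  rows <- purrr::map(split(traces, traces$object_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    present <- phases %in% tr$phase
    if (!all(present)) {
      abort(sprintf("object %s is missing phase(s): %s",
                    as.character(tr$object_id[1]),
                    paste(phases[!present], collapse = ", ")))
    }
    # drop the first transition_frames frames of every phase after the first
    runs <- rle(tr$phase)
    starts <- cumsum(c(1, head(runs$lengths, -1)))
    drop <- unlist(purrr::map2(starts[-1], runs$lengths[-1], function(s, len) {
      s + seq_len(min(transition_frames, len - 1)) - 1
    }))
    use <- setdiff(seq_len(nrow(tr)), drop)
    keep <- tr[use, ]
    phase_mean <- tapply(keep$intensity, keep$phase, mean)
    surface <- mean(phase_mean[c("baseline1", "baseline2", "baseline3")])
    total <- unname(phase_mean["NH4Cl"])
    intracellular <- total - surface
    flag <- "ok"
    if (total <= 0) {
      flag <- "nonpositive_total"
    } else if (surface > total * (1 + noise_tol)) {
      flag <- "surface_exceeds_total"
    }
    tibble(
      object_id = tr$object_id[1],
      compartment = if ("compartment" %in% names(tr)) tr$compartment[1] else NA_character_,
      total = total,
      surface = surface,
      intracellular = intracellular,
      intracellular_pct = if (total > 0) 100 * intracellular / total else NA_real_,
      quench_pct = if (surface > 0) {
        100 * (surface - unname(phase_mean["pH5.5"])) / surface
      } else NA_real_,
      flag = flag
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("pool_estimate", class(out))
  out
}

#' Spine share of the intracellular pool
#'
#' Percentage of the summed intracellular pool residing in spine objects:
#' `100 * sum(intracellular, spines) / sum(intracellular, all objects)`.
#'
#' @param pools A [estimate_pools()] table with a `compartment` column
#'   (`spine` / `shaft`).
#' @return Tibble with `spine_share_pct`, `intracellular_spine`,
#'   `intracellular_total`, `flag` (`undefined_zero_total` when the total
#'   intracellular pool is not positive).
#' @export
#' @examples
#' pools <- tibble::tibble(object_id = 1:2, compartment = c("spine", "shaft"),
#'                         intracellular = c(30, 70))
#' partition_spine_shaft(pools)$spine_share_pct # 30
partition_spine_shaft <- function(pools) {
  check_columns(pools, c("compartment", "intracellular"), "pool estimates")
  intra_total <- sum(pools$intracellular)
  intra_spine <- sum(pools$intracellular[pools$compartment == "spine"])
  tibble(
    spine_share_pct = if (intra_total > 0) 100 * intra_spine / intra_total else NA_real_,
    intracellular_spine = intra_spine,
    intracellular_total = intra_total,
    flag = if (intra_total > 0) "ok" else "undefined_zero_total"
  )
}
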