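#' Construct ground truth for dual-channel localization fields
#'
#' Plans a set of synapses, each carrying one or more pairs of subsynaptic
#' domains (SSDs): a presynaptic scaffold (RIM-like) SSD and a postsynaptic
#' receptor (GluA-like) SSD whose centroid sits at `offset_nm` from its
#' partner in a random direction — the trans-synaptic nanocolumn geometry.
#'
#' @param config A [sim_config()] (field size, seed for the layout).
#' @param n_synapses Number of synapses, laid out on a jittered grid.
#' @param ssd_pairs_per_synapse SSD pairs per synapse (recycled).
#' @param offset_nm Planted RIM-to-GluA centroid distance in nanometres.
#' @param locs_per_ssd Expected localization count per SSD per channel
#'   (Poisson mean).
#' @param ssd_radius_nm SSD radius in nm; member localizations are drawn
#'   isotropic Gaussian with sd `ssd_radius_nm / 2`.
#' @param background_density Uniform background, localizations per um^2.
#' @return Tibble of class `nanocolumn_truth` (one row per SSD pair) with
#'   attributes carrying the scalar parameters.
#' @export
nanocolumn_truth <- function(config, n_synapses = 10,
                             ssd_pairs_per_synapse = 1,
                             offset_nm = 60,
                             locs_per_ssd = 100,
                             ssd_radius_nm = 35,
                             background_density = 0) {
  stopifnot(inherits(config, "sim_config"))
  if (background_density < 0) abort("`background_density` must be non-negative")
  if (locs_per_ssd <= 0) abort("`locs_per_ssd` must be positive")
  if (any(offset_nm < 0)) abort("`offset_nm` must be non-negative")
  set_sim_seed(config, offset = 404L)

  field_nm <- um_to_nm(config$field_size)
  # jittered grid layout keeps synapses well separated
  n_side <- ceiling(sqrt(n_synapses))
  gx <- (rep(seq_len(n_side), n_side) - 0.5) / n_side * field_nm[1]
  gy <- (rep(seq_len(n_side), each = n_side) - 0.5) / n_side * field_nm[2]
  keep <- seq_len(n_synapses)
  centers <- cbind(gx[keep], gy[keep]) +
    matrix(runif(2 * n_synapses, -100, 100), ncol = 2)

  n_pairs <- rep_len(ssd_pairs_per_synapse, n_synapses)
  rows <- purrr::map(seq_len(n_synapses), function(s) {
    k <- n_pairs[s]
    # RIM SSD centres spread around the synapse centre; multiple pairs sit
    # at equally spaced angles on a 150 nm ring so they stay resolvable.
    # The paired GluA SSD is displaced by offset_nm in a random direction.
    if (k == 1) {
      jit <- matrix(runif(2, -80, 80), ncol = 2)
    } else {
      phi <- 2 * pi * (seq_len(k) - 1) / k + runif(1, 0, 2 * pi)
      jit <- cbind(150 * cos(phi), 150 * sin(phi)) +
        matrix(runif(2 * k, -20, 20), ncol = 2)
    }
    theta <- runif(k, 0, 2 * pi)
    off <- rep_len(offset_nm, k)
    tibble(
      synapse_id = s, pair_id = seq_len(k),
      rim_x_nm = centers[s, 1] + jit[, 1],
      rim_y_nm = centers[s, 2] + jit[, 2],
      glua_x_nm = centers[s, 1] + jit[, 1] + off * cos(theta),
      glua_y_nm = centers[s, 2] + jit[, 2] + off * sin(theta),
      offset_nm = off
    )
  })
  out <- bind_rows(rows)
  attr(out, "locs_per_ssd") <- locs_per_ssd
  attr(out, "ssd_radius_nm") <- ssd_radius_nm
  attr(out, "background_density") <- background_density
  attr(out, "synapse_centers_nm") <- centers
  class(out) <- c("nanocolumn_truth", class(out))
  out
}

# draw one channel's localization table from a set of SSD centres
.sim_channel_locs <- function(centers_x, centers_y, channel, locs_per_ssd,
                              ssd_sd, background_density, field_nm, n_frames) {
  counts <- rpois(length(centers_x), locs_per_ssd)
  xs <- unlist(purrr::map2(centers_x, counts, ~ rnorm(.y, .x, ssd_sd)))
  ys <- unlist(purrr::map2(centers_y, counts, ~ rnorm(.y, .x, ssd_sd)))
  area_um2 <- prod(field_nm) / 1e6
  n_bg <- rpois(1, background_density * area_um2)
  xs <- c(xs, runif(n_bg, 0, field_nm[1]))
  ys <- c(ys, runif(n_bg, 0, field_nm[2]))
  tibble(
    x_nm = xs, y_nm = ys,
    frame = sample.int(n_frames, length(xs), replace = TRUE),
    channel = channel
  )
}

#' Simulate dual-channel SMLM localization tables with planted SSD pairs
#'
#' Draws `Poisson(locs_per_ssd)` localizations per SSD from an isotropic
#' Gaussian of sd `ssd_radius_nm / 2` around each planted centroid, adds
#' uniform background at `background_density` localizations per um^2, and
#' returns one table per channel in the common SMLM CSV layout
#' (`x_nm`, `y_nm`, `frame`, `channel`).
#'
#' @param config A [sim_config()].
#' @param truth A [nanocolumn_truth()] table.
#' @param n_frames Number of acquisition frames for the `frame` column.
#' @return List of class `smlm_sim`: `rim`, `glua` localization tibbles and
#'   `truth`.
#' @export
#' @examples
#' cfg <- sim_config(1, field_size = c(4, 4))
#' sim <- simulate_localizations(cfg, nanocolumn_truth(cfg, n_synapses = 4))
#' nrow(sim$rim)
simulate_localizations <- function(config, truth, n_frames = 40000L) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "nanocolumn_truth"))
  set_sim_seed(config, offset = 405L)
  field_nm <- um_to_nm(config$field_size)
  ssd_sd <- attr(truth, "ssd_radius_nm") / 2
  lps <- attr(truth, "locs_per_ssd")
  bg <- attr(truth, "background_density")
  rim <- .sim_channel_locs(truth$rim_x_nm, truth$rim_y_nm, "RIM",
                           lps, ssd_sd, bg, field_nm, n_frames)
  glua <- .sim_channel_locs(truth$glua_x_nm, truth$glua_y_nm, "GluA",
                            lps, ssd_sd, bg, field_nm, n_frames)
  structure(list(rim = rim, glua = glua, truth = truth), class = "smlm_sim")
}
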