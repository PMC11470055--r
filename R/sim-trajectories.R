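#' Build a synapse mask with disc-shaped synaptic areas
#'
#' Creates a binary raster (rows = y, columns = x, pixel value 1 inside a
#' synapse) together with its pixel size, in the coordinate frame used by
#' the trajectory tables (origin at (0, 0), x to the right, y downwards in
#' row direction). Used both by the trajectory generator (to plant synaptic
#' tracks) and by the synaptic-sorting analysis.
#'
#' @param field_size Length-2 numeric, field size in micrometres.
#' @param centers Two-column matrix (or data frame) of synapse centre
#'   coordinates in micrometres.
#' @param radius_um Synapse disc radius in micrometres (default 0.3 um,
#'   a typical postsynaptic-marker punctum).
#' @param pixel_size_um Raster pixel size in micrometres (default 0.1).
#' @return An object of class `synapse_mask`: list with `mask` (integer
#'   matrix), `pixel_size_um`, and `centers`.
#' @export
#' @examples
#' m <- synapse_mask(c(5, 5), centers = cbind(2.5, 2.5), radius_um = 0.5)
#' sum(m$mask) > 0
synapse_mask <- function(field_size, centers, radius_um = 0.3,
                         pixel_size_um = 0.1) {
  check_positive_scalar(radius_um, "radius_um")
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  centers <- as.matrix(centers)
  if (ncol(centers) != 2) abort("`centers` must have two columns (x, y) in micrometres")
  ncol_px <- ceiling(field_size[1] / pixel_size_um)
  nrow_px <- ceiling(field_size[2] / pixel_size_um)
  # pixel-center convention: pixel (r, c) covers
  # x in [(c-1)*px, c*px), y in [(r-1)*px, r*px)
  cx <- (seq_len(ncol_px) - 0.5) * pixel_size_um
  cy <- (seq_len(nrow_px) - 0.5) * pixel_size_um
  mask <- matrix(0L, nrow = nrow_px, ncol = ncol_px)
  for (i in seq_len(nrow(centers))) {
    dx <- outer(rep(1, nrow_px), (cx - centers[i, 1])^2)
    dy <- outer((cy - centers[i, 2])^2, rep(1, ncol_px))
    mask[dx + dy <= radius_um^2] <- 1L
  }
  structure(
    list(mask = mask, pixel_size_um = pixel_size_um, centers = centers),
    class = "synapse_mask"
  )
}

# single Brownian/confined/immobile trajectory (positions in um, no noise)
.sim_one_track <- function(model, n_points, start, D, r_conf, dt) {
  if (model == "immobile") {
    return(cbind(x = rep(start[1], n_points), y = rep(start[2], n_points)))
  }
  step_sd <- sqrt(2 * D * dt)
  steps <- matrix(rnorm(2 * (n_points - 1), sd = step_sd), ncol = 2)
  if (model == "brownian") {
    xy <- rbind(c(0, 0), apply(steps, 2, cumsum))
    return(cbind(x = start[1] + xy[, 1], y = start[2] + xy[, 2]))
  }
  # confined: Brownian steps reflected at a circular boundary of radius
  # r_conf centred on the start position
  pos <- matrix(0, nrow = n_points, ncol = 2)
  for (i in 2:n_points) {
    p <- pos[i - 1, ] + steps[i - 1, ]
    r <- sqrt(sum(p^2))
    while (r > r_conf) {
      p <- p * (2 * r_conf - r) / r # radial reflection at the boundary
      r <- abs(2 * r_conf - r)
    }
    pos[i, ] <- p
  }
  cbind(x = start[1] + pos[, 1], y = start[2] + pos[, 2])
}

#' Simulate single-molecule trajectories with known motion models
#'
#' Generates 2D trajectories from three motion models at the camera frame
#' interval of `config`:
#' * `brownian` — free diffusion, per-axis step variance `2 * D * dt`;
#' * `confined` — Brownian steps reflected at a circular boundary of radius
#'   `r_conf` (the mean square displacement of this process saturates, as
#'   for molecules trapped in a subsynaptic area);
#' * `immobile` — a fixed point.
#'
#' Localization noise is added independently per coordinate and per frame
#' (`config$loc_noise_sd`). Trajectory lengths are drawn uniformly over
#' `track_length` so that downstream length filters are exercised from both
#' sides. When a `synapse_mask` is supplied, a fraction `frac_at_synapse`
#' of the confined and immobile tracks is seeded at synapse centres, and
#' the realized fraction of frames inside the mask is recorded as truth.
#'
#' @param config A [sim_config()].
#' @param n_per_class Named integer vector with any of `brownian`,
#'   `confined`, `immobile`: number of trajectories of each class.
#' @param D Named numeric vector of diffusion coefficients (um^2/s) for
#'   `brownian` and `confined` classes.
#' @param r_conf Confinement radius in micrometres (confined class).
#' @param track_length Length-2 integer range; lengths drawn uniformly.
#' @param masks Optional [synapse_mask()].
#' @param frac_at_synapse Fraction of confined+immobile tracks seeded at a
#'   synapse centre when `masks` is given.
#' @return List of class `spt_sim` with elements `tracks` (tibble:
#'   `track_id`, `frame`, `x_um`, `y_um`) and `truth` (tibble: `track_id`,
#'   `motion_model`, `D_true`, `r_conf_true`, `n_points`,
#'   `inside_synapse_fraction_true`).
#' @export
#' @examples
#' sim <- simulate_trajectories(sim_config(1), n_per_class = c(brownian = 3))
#' head(sim$tracks)
#' sim$truth
simulate_trajectories <- function(config,
                                  n_per_class = c(brownian = 10, confined = 10, immobile = 10),
                                  D = c(brownian = 0.2, confined = 0.1, immobile = 0),
                                  r_conf = 0.1,
                                  track_length = c(10, 60),
                                  masks = NULL,
                                  frac_at_synapse = 0) {
  stopifnot(inherits(config, "sim_config"))
  check_positive_scalar(config$frame_interval, "frame_interval")
  if (any(n_per_class < 0)) abort("`n_per_class` must be non-negative")
  bad <- setdiff(names(n_per_class), c("brownian", "confined", "immobile"))
  if (length(bad) > 0) abort(paste0("unknown motion class: ", paste(bad, collapse = ", ")))
  check_positive_scalar(r_conf, "r_conf")
  set_sim_seed(config, offset = 101L)

  dt <- config$frame_interval
  models <- rep(names(n_per_class), times = n_per_class)
  n_tracks <- length(models)
  if (n_tracks == 0) {
    return(structure(list(
      tracks = tibble(track_id = integer(), frame = integer(),
                      x_um = double(), y_um = double()),
      truth = tibble(track_id = integer(), motion_model = character(),
                     D_true = double(), r_conf_true = double(),
                     n_points = integer(),
                     inside_synapse_fraction_true = double())
    ), class = "spt_sim"))
  }

  lengths <- track_length[1] +
    sample.int(track_length[2] - track_length[1] + 1L, n_tracks, replace = TRUE) - 1L
  starts <- cbind(runif(n_tracks, 0, config$field_size[1]),
                  runif(n_tracks, 0, config$field_size[2]))
  if (!is.null(masks) && frac_at_synapse > 0) {
    stopifnot(inherits(masks, "synapse_mask"))
    seeded <- models %in% c("confined", "immobile") &
      runif(n_tracks) < frac_at_synapse
    if (any(seeded)) {
      idx <- sample(nrow(masks$centers), sum(seeded), replace = TRUE)
      starts[seeded, ] <- masks$centers[idx, , drop = FALSE]
    }
  }

  tracks <- vector("list", n_tracks)
  inside_frac <- rep(NA_real_, n_tracks)
  for (i in seq_len(n_tracks)) {
    Di <- unname(D[models[i]])
    if (is.na(Di)) Di <- 0
    xy <- .sim_one_track(models[i], lengths[i], starts[i, ], Di, r_conf, dt)
    if (config$loc_noise_sd > 0) {
      xy <- xy + matrix(rnorm(length(xy), sd = config$loc_noise_sd), ncol = 2)
    }
    if (!is.null(masks)) {
      inside_frac[i] <- mean(point_in_mask(xy[, 1], xy[, 2], masks))
    }
    tracks[[i]] <- tibble(
      track_id = i, frame = seq_len(lengths[i]),
      x_um = xy[, 1], y_um = xy[, 2]
    )
  }

  truth <- tibble(
    track_id = seq_len(n_tracks),
    motion_model = models,
    D_true = unname(ifelse(is.na(D[models]), 0, D[models])),
    r_conf_true = ifelse(models == "confined", r_conf, NA_real_),
    n_points = as.integer(lengths),
    inside_synapse_fraction_true = inside_frac
  )
  structure(list(tracks = bind_rows(tracks), truth = truth), class = "spt_sim")
}
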