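#' Single-particle-tracking analysis configuration
#'
#' Holds the thresholds of the motion-classification pipeline. With
#' `D_threshold = "auto"` the immobility threshold is derived from the
#' image spatial resolution: a molecule is immobile when it explores less
#' than the resolution-limited area during the time used to fit the
#' initial MSD slope, i.e.
#' `D_threshold = resolution^2 / (4 * n_fit_points * dt)`.
#' With the defaults (0.04 um resolution, 4 fit points, 20 ms frames) this
#' is exactly 0.005 um^2/s.
#'
#' @param dt Frame interval in seconds (default 0.02).
#' @param n_fit_points Number of initial MSD points in the linear
#'   diffusion fit (default 4).
#' @param D_threshold Immobility threshold in um^2/s, or `"auto"`.
#' @param tau_threshold Confinement time-constant cut in seconds: confined
#'   if the fitted tau is at or below this value, diffusive above. Default
#'   0.1 s, half the 200 ms MSD window used for the confinement fit.
#' @param min_points Minimum trajectory length in points (default 10,
#'   i.e. at least 200 ms at 20 ms frames).
#' @param synaptic_fraction_cut Fraction of a trajectory's duration that
#'   must be spent inside a synaptic area for the track to count as
#'   synaptic (default 0.5, strict inequality).
#' @param resolution Image spatial resolution in micrometres (default
#'   0.04), used by the `"auto"` threshold.
#' @param conf_fit_lags Number of MSD lags in the confinement fit
#'   (default 10, i.e. a 200 ms window at 20 ms frames).
#' @return Object of class `spt_config`.
#' @export
#' @examples
#' spt_config()$D_threshold # 0.005
spt_config <- function(dt = 0.02, n_fit_points = 4, D_threshold = "auto",
                       tau_threshold = 0.1, min_points = 10,
                       synaptic_fraction_cut = 0.5, resolution = 0.04,
                       conf_fit_lags = 10) {
  check_positive_scalar(dt, "dt")
  check_positive_scalar(resolution, "resolution")
  if (n_fit_points < 2) abort("`n_fit_points` must be at least 2")
  if (identical(D_threshold, "auto")) {
    D_threshold <- resolution^2 / (4 * n_fit_points * dt)
  }
  check_positive_scalar(D_threshold, "D_threshold")
  check_positive_scalar(tau_threshold, "tau_threshold")
  if (min_points < 2) abort("`min_points` must be at least 2")
  structure(
    list(dt = dt, n_fit_points = n_fit_points, D_threshold = D_threshold,
         tau_threshold = tau_threshold, min_points = min_points,
         synaptic_fraction_cut = synaptic_fraction_cut,
         resolution = resolution, conf_fit_lags = conf_fit_lags),
    class = "spt_config"
  )
}

#' Compute the time-averaged mean square displacement of one trajectory
#'
#' For each lag `k` the MSD is the average squared 2D displacement over
#' all pairs of positions separated by `k` frames (time-averaged,
#' overlapping pairs); the number of pairs entering each lag is recorded.
#' Frame gaps are respected: only pairs whose frame numbers differ by
#' exactly `k` contribute.
#'
#' @param traj Data frame for a single track with columns `frame`, `x_um`,
#'   `y_um` (a `track_id` column, if present, is carried through).
#' @param max_lag Largest lag in frames; must be smaller than the number
#'   of points.
#' @param dt Frame interval in seconds.
#' @return Tibble of class `msd_curve` with columns `lag` (frames),
#'   `lag_s` (seconds), `msd` (um^2), `n_pairs`.
#' @export
#' @examples
#' traj <- data.frame(frame = 1:2, x_um = c(0, 0.1), y_um = c(0, 0))
#' compute_msd(traj, max_lag = 1)$msd # 0.01
compute_msd <- function(traj, max_lag, dt = 0.02) {
  check_columns(traj, c("frame", "x_um", "y_um"), "trajectory")
  n <- nrow(traj)
  if (any(diff(traj$frame) <= 0)) abort("`frame` must be strictly increasing")
  if (max_lag >= n) {
    id <- if ("track_id" %in% names(traj)) traj$track_id[1] else "<unnamed>"
    abort(sprintf("max_lag (%d) must be smaller than track length (%d) for track %s",
                  max_lag, n, as.character(id)))
  }
  f <- traj$frame
  x <- traj$x_um
  y <- traj$y_um
  msd <- n_pairs <- numeric(max_lag)
  for (k in seq_len(max_lag)) {
    j <- match(f + k, f)
    ok <- !is.na(j)
    n_pairs[k] <- sum(ok)
    msd[k] <- if (any(ok)) {
      mean((x[j[ok]] - x[ok])^2 + (y[j[ok]] - y[ok])^2)
    } else NA_real_
  }
  out <- tibble(lag = seq_len(max_lag), lag_s = seq_len(max_lag) * dt,
                msd = msd, n_pairs = as.integer(n_pairs))
  attr(out, "dt") <- dt
  if ("track_id" %in% names(traj)) attr(out, "track_id") <- traj$track_id[1]
  class(out) <- c("msd_curve", class(out))
  out
}

#' Estimate the diffusion coefficient from the initial MSD slope
#'
#' Ordinary least-squares line through the first `n_fit_points` (lag,
#' MSD) pairs with a free intercept — the intercept absorbs the constant
#' MSD offset contributed by localization noise, leaving the slope
#' unbiased. For 2D motion `D = slope / 4`. A negative slope is clamped
#' to `D = 0` and flagged.
#'
#' @param msd An [compute_msd()] curve (or data frame with `lag_s`, `msd`).
#' @param cfg An [spt_config()].
#' @return List with `D` (um^2/s), `intercept` (um^2), `clamped` flag.
#' @export
#' @examples
#' msd <- tibble::tibble(lag_s = (1:4) * 0.02, msd = 4 * 0.1 * (1:4) * 0.02)
#' fit_linear_diffusion(msd, spt_config())$D # 0.1
fit_linear_diffusion <- function(msd, cfg = spt_config()) {
  check_columns(msd, c("lag_s", "msd"), "MSD curve")
  k <- cfg$n_fit_points
  if (nrow(msd) < k) {
    abort(sprintf("MSD curve has %d lags but the linear fit needs %d", nrow(msd), k))
  }
  d <- msd[seq_len(k), ]
  fit <- lm(msd ~ lag_s, data = d)
  slope <- unname(coef(fit)[2])
  list(
    D = max(slope / 4, 0),
    intercept = unname(coef(fit)[1]),
    clamped = slope < 0
  )
}

#' Fit the confined-diffusion MSD model
#'
#' Nonlinear least squares of
#' `MSD(t) = (4/3) * r_conf^2 * (1 - exp(-t / tau))`
#' over the supplied lags (classification uses the first
#' `conf_fit_lags` lags, a 200 ms window at default settings). The model
#' saturates at `(4/3) r_conf^2`; its time constant relates to the
#' confined diffusion coefficient by `tau = r_conf^2 / (3 * D_conf)`.
#'
#' @param msd An MSD curve (columns `lag_s`, `msd`).
#' @param cfg An [spt_config()]; the fit uses its first `conf_fit_lags`
#'   lags (or all available lags if fewer).
#' @return Object of class `confinement_fit`: list with `r_conf` (um),
#'   `tau` (s), `D_conf = r_conf^2 / (3 tau)`, `converged`, `rss`, and the
#'   fitted window. Non-convergence returns `converged = FALSE` with `NA`
#'   parameters (treated downstream as diffusive).
#' @export
fit_confinement <- function(msd, cfg = spt_config()) {
  check_columns(msd, c("lag_s", "msd"), "MSD curve")
  d <- msd[seq_len(min(cfg$conf_fit_lags, nrow(msd))), ]
  d <- d[is.finite(d$msd), ]
  if (nrow(d) < 3) abort("confinement fit needs at least 3 finite MSD lags")
  if (all(d$msd <= 0)) {
    abort("all-zero MSD curve: track should have been classified immobile")
  }
  plateau <- max(d$msd)
  fit <- nls_lm_fit(
    par = c(r_conf = sqrt(0.75 * plateau), tau = max(d$lag_s) / 5),
    resid_fn = function(p) {
      d$msd - (4 / 3) * p[["r_conf"]]^2 * (1 - exp(-d$lag_s / p[["tau"]]))
    },
    lower = c(r_conf = 1e-6, tau = 1e-6),
    maxiter = 200
  )
  if (is.null(fit)) {
    out <- list(r_conf = NA_real_, tau = NA_real_, D_conf = NA_real_,
                converged = FALSE, rss = NA_real_, window = d)
  } else {
    p <- fit$par
    out <- list(r_conf = unname(p["r_conf"]), tau = unname(p["tau"]),
                D_conf = unname(p["r_conf"]^2 / (3 * p["tau"])),
                converged = TRUE, rss = fit$rss, window = d)
  }
  class(out) <- "confinement_fit"
  out
}

#' @export
print.confinement_fit <- function(x, ...) {
  cat("<confinement_fit>")
  if (x$converged) {
    cat(sprintf(" r_conf = %.4g um, tau = %.4g s, D_conf = %.4g um^2/s\n",
                x$r_conf, x$tau, x$D_conf))
  } else {
    cat(" did not converge (treated as diffusive)\n")
  }
  invisible(x)
}
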