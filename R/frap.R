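#' Normalize raw FRAP traces
#'
#' Background-subtracts and bleach-corrects each region trace, then maps
#' it affinely so the pre-bleach mean equals 1 and the first post-bleach
#' value equals 0. Bleach correction divides by the unbleached reference
#' region (background-subtracted, normalized to its own pre-bleach mean),
#' which removes acquisition photobleaching. Regions whose reference
#' signal crosses the background (division by a non-positive number) are
#' excluded with reason `excluded_reference`.
#'
#' @param traces Tibble with columns `region_id`, `frame`,
#'   `roi_intensity`, `bg_intensity`, `ref_intensity` (a `region_class`
#'   column is carried through). Accepts the `traces` element of a
#'   [simulate_frap_traces()] result directly.
#' @param bleach_frame Index of the first post-bleach frame (at least 11:
#'   ten pre-bleach frames must exist).
#' @param dt Seconds per frame.
#' @return Tibble of class `frap_normalized`: `region_id`,
#'   (`region_class`,) `frame`, `t` (seconds from bleach), `F`
#'   (dimensionless), `phase` (`pre`/`post`), plus per-region columns
#'   `bleach_depth` and `qc` (`included` or `excluded_reference`; depth
#'   and negativity exclusions are applied by [frap_qc()]).
#' @export
#' @examples
#' sim <- simulate_frap_traces(sim_config(1), frap_truth(1))
#' norm <- normalize_frap(sim$traces, sim$bleach_frame, sim$dt)
#' head(norm)
normalize_frap <- function(traces, bleach_frame, dt = 1) {
  if (inherits(traces, "frap_sim")) {
    if (missing(bleach_frame)) bleach_frame <- traces$bleach_frame
    dt <- traces$dt
    traces <- traces$traces
  }
  check_columns(traces, c("region_id", "frame", "roi_intensity",
                          "bg_intensity", "ref_intensity"), "FRAP traces")
  if (bleach_frame < 11) abort("`bleach_frame` must be >= 11 (ten pre-bleach frames)")

  per_region <- split(traces, traces$region_id)
  rows <- purrr::map(per_region, function(tr) {
    tr <- tr[order(tr$frame), ]
    pre <- tr$frame < bleach_frame
    ref_corr <- tr$ref_intensity - tr$bg_intensity
    qc <- "included"
    if (any(ref_corr <= 0)) {
      qc <- "excluded_reference"
      F_norm <- rep(NA_real_, nrow(tr))
      depth <- NA_real_
    } else {
      corr <- (tr$roi_intensity - tr$bg_intensity) /
        (ref_corr / mean(ref_corr[pre]))
      pre_mean <- mean(corr[pre])
      post0 <- corr[tr$frame == bleach_frame]
      depth <- 1 - post0 / pre_mean
      F_norm <- (corr - post0) / (pre_mean - post0)
    }
    out <- tibble(
      region_id = tr$region_id[1],
      frame = tr$frame,
      t = (tr$frame - bleach_frame) * dt,
      F = F_norm,
      phase = ifelse(pre, "pre", "post"),
      bleach_depth = depth,
      qc = qc
    )
    if ("region_class" %in% names(tr)) out$region_class <- tr$region_class
    out
  })
  out <- bind_rows(rows)
  class(out) <- c("frap_normalized", class(out))
  out
}

#' Quality-filter normalized FRAP traces
#'
#' Applies the two exclusion rules: bleaching depth below `min_depth`
#' (default 50%) excludes a region as `excluded_depth`; any post-bleach
#' normalized value below `-negative_tol` excludes it as
#' `excluded_negative`. The small tolerance keeps traces whose noise
#' merely dips below zero.
#'
#' @param norm A [normalize_frap()] result.
#' @param min_depth Minimum bleach depth (default 0.5).
#' @param negative_tol Tolerance below zero for post-bleach values
#'   (default 0.02).
#' @return Tibble with one row per region: `region_id`, `bleach_depth`,
#'   `qc` in `included`, `excluded_depth`, `excluded_negative`,
#'   `excluded_reference`.
#' @export
frap_qc <- function(norm, min_depth = 0.5, negative_tol = 0.02) {
  check_columns(norm, c("region_id", "F", "phase", "bleach_depth", "qc"),
                "normalized traces")
  per_region <- split(norm, norm$region_id)
  rows <- purrr::map(per_region, function(tr) {
    qc <- tr$qc[1]
    if (qc == "included") {
      if (is.na(tr$bleach_depth[1]) || tr$bleach_depth[1] < min_depth) {
        qc <- "excluded_depth"
      } else if (any(tr$F[tr$phase == "post"] < -negative_tol, na.rm = TRUE)) {
        qc <- "excluded_negative"
      }
    }
    tibble(region_id = tr$region_id[1],
           bleach_depth = tr$bleach_depth[1], qc = qc)
  })
  bind_rows(rows)
}

# residuals of the double-exponential recovery model
.frap_model <- function(t, F0, p, tauf, q, taus) {
  F0 + p * (1 - exp(-t / tauf)) + q * (1 - exp(-t / taus))
}

#' Fit the double-exponential FRAP recovery model to one trace
#'
#' Bounded nonlinear least squares of
#' `F(t) = F0 + p (1 - exp(-t/tauf)) + q (1 - exp(-t/taus))`
#' on the post-bleach samples, with `F0, p, q >= 0`,
#' `F0 + p + q <= 1`, and `taus` capped at five times the trace duration
#' (identifiability guard). Three starts jitter the initial time
#' constants by factors 0.5, 1, 2; the best converged fit is kept and the
#' pools are relabeled if needed so `tauf < taus`. The slow-pool fraction
#' is the fitted `q`.
#'
#' @param t Time from bleach, seconds (post-bleach samples, `t >= 0`).
#' @param F Normalized fluorescence at `t`.
#' @return Object of class `frap_fit`: list with `F0`, `p`, `tauf`, `q`,
#'   `taus`, `slow_pool_fraction`, `converged`, `degenerate`, `rss`,
#'   `n`, and the data. Use [tidy()] / [glance()] for tabular access.
#' @export
#' @examples
#' t <- seq(0, 300, by = 2)
#' y <- 0.5 * (1 - exp(-t / 5)) + 0.3 * (1 - exp(-t / 120))
#' coef(fit_frap_trace(t, y))
fit_frap_trace <- function(t, F) {
  ok <- is.finite(t) & is.finite(F) & t >= 0
  t <- t[ok]
  F <- F[ok]
  if (length(t) < 20) abort("FRAP fit needs at least 20 post-bleach samples")
  dur <- max(t)

  out <- list(F0 = 0, p = 0, tauf = NA_real_, q = 0, taus = NA_real_,
              slow_pool_fraction = 0, converged = FALSE, degenerate = FALSE,
              rss = NA_real_, n = length(t), t = t, F = F)
  class(out) <- "frap_fit"

  if (sd(F) < 1e-9 || max(abs(F)) < 1e-9) {
    # flat trace: no recovery to decompose
    out$converged <- TRUE
    out$degenerate <- TRUE
    out$F0 <- mean(F)
    out$rss <- sum((F - mean(F))^2)
    return(out)
  }

  plateau <- max(mean(tail(F, max(3, round(length(F) / 10)))), 0.1)
  lower <- c(F0 = 0, p = 0, tauf = 1e-4, q = 0, taus = 1e-4)
  upper <- c(F0 = 1, p = 1, tauf = 5 * dur, q = 1, taus = 5 * dur)
  resid_fn <- function(par) {
    F - .frap_model(t, par[["F0"]], par[["p"]], par[["tauf"]],
                    par[["q"]], par[["taus"]])
  }
  best <- NULL
  for (jit in c(1, 0.5, 2)) {
    start <- c(F0 = 0.01, p = 0.6 * plateau, tauf = 0.1 * dur * jit,
               q = 0.4 * plateau, taus = min(0.6 * dur * jit, 5 * dur))
    fit <- nls_lm_fit(start, resid_fn, lower = lower, upper = upper)
    if (!is.null(fit) && (is.null(best) || fit$rss < best$rss)) best <- fit
  }
  if (is.null(best)) return(out)

  cf <- as.list(best$par)
  # enforce the sum constraint with a penalized refinement if violated
  if (cf$F0 + cf$p + cf$q > 1 + 1e-6) {
    obj <- function(par) {
      pr <- setNames(as.list(par), c("F0", "p", "tauf", "q", "taus"))
      r <- F - .frap_model(t, pr$F0, pr$p, pr$tauf, pr$q, pr$taus)
      sum(r^2) + 1e4 * max(0, pr$F0 + pr$p + pr$q - 1)^2
    }
    opt <- optim(unlist(cf), obj, method = "L-BFGS-B",
                 lower = c(0, 0, 1e-4, 0, 1e-4),
                 upper = c(1, 1, 5 * dur, 1, 5 * dur))
    cf <- setNames(as.list(opt$par), c("F0", "p", "tauf", "q", "taus"))
    best$rss <- sum((F - .frap_model(t, cf$F0, cf$p, cf$tauf, cf$q, cf$taus))^2)
  }
  # relabel pools so the fast pool is the fast one
  if (cf$tauf > cf$taus) {
    cf[c("p", "tauf", "q", "taus")] <- cf[c("q", "taus", "p", "tauf")]
  }
  out$F0 <- cf$F0
  out$p <- cf$p
  out$tauf <- cf$tauf
  out$q <- cf$q
  out$taus <- cf$taus
  out$slow_pool_fraction <- cf$q
  out$converged <- TRUE
  out$rss <- best$rss
  out
}

#' @export
coef.frap_fit <- function(object, ...) {
  c(F0 = object$F0, p = object$p, tauf = object$tauf,
    q = object$q, taus = object$taus)
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("<frap_fit>")
  if (!x$converged) {
    cat(" did not converge\n")
  } else if (x$degenerate) {
    cat(" degenerate (flat trace), p = q = 0\n")
  } else {
    cat(sprintf(
      " F0 = %.3f, p = %.3f (tauf = %.3g s), q = %.3f (taus = %.3g s)\n",
      x$F0, x$p, x$tauf, x$q, x$taus))
    cat(sprintf("  slow pool fraction = %.3f, rss = %.3g, n = %d\n",
                x$slow_pool_fraction, x$rss, x$n))
  }
  invisible(x)
}

#' Fit FRAP recovery for every included region
#'
#' Maps [fit_frap_trace()] over the regions of a normalized trace table,
#' using only regions whose [frap_qc()] decision is `included`.
#'
#' @param norm A [normalize_frap()] result.
#' @param qc Optional [frap_qc()] table; computed with defaults if absent.
#' @return Tibble of class `frap_fit_table`: one row per included region
#'   with the fitted parameters, `slow_pool_fraction`, diagnostics, and a
#'   list-column `fit` holding the `frap_fit` objects.
#' @export
fit_frap <- function(norm, qc = NULL) {
  if (is.null(qc)) qc <- frap_qc(norm)
  included <- qc$region_id[qc$qc == "included"]
  if (length(included) == 0) abort("no region passed quality control")
  rows <- purrr::map(included, function(id) {
    tr <- norm[norm$region_id == id & norm$phase == "post", ]
    fit <- fit_frap_trace(tr$t, tr$F)
    tibble(
      region_id = id,
      region_class = if ("region_class" %in% names(tr)) tr$region_class[1] else NA_character_,
      F0 = fit$F0, p = fit$p, tauf = fit$tauf, q = fit$q, taus = fit$taus,
      slow_pool_fraction = fit$slow_pool_fraction,
      converged = fit$converged, degenerate = fit$degenerate,
      rss = fit$rss, n = fit$n, fit = list(fit)
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("frap_fit_table", class(out))
  out
}

#' Initial surface intensity of a region
#'
#' Background-subtracted mean intensity of the first frame, per region —
#' the pre-bleach surface signal. Negative values (background exceeding
#' the ROI) are returned as-is with a warning, not clamped.
#'
#' @param traces Raw trace tibble as in [normalize_frap()].
#' @return Tibble `region_id`, `surface_intensity`.
#' @export
surface_intensity <- function(traces) {
  if (inherits(traces, "frap_sim")) traces <- traces$traces
  check_columns(traces, c("region_id", "frame", "roi_intensity", "bg_intensity"),
                "FRAP traces")
  first <- traces %>%
    group_by(.data$region_id) %>%
    filter(.data$frame == min(.data$frame)) %>%
    summarise(surface_intensity = mean(.data$roi_intensity) - mean(.data$bg_intensity),
              .groups = "drop")
  if (any(first$surface_intensity < 0)) {
    warn("some regions have background above the ROI signal (negative surface intensity)")
  }
  first
}

#' Population-average recovery curve and slow-pool distribution
#'
#' Resamples every included normalized post-bleach trace onto a common
#' time base by linear interpolation and returns the per-time mean with
#' its standard error, together with the per-region slow-pool fractions.
#'
#' @param norm A [normalize_frap()] result.
#' @param fits A [fit_frap()] table (non-converged or degenerate fits are
#'   dropped from the slow-pool distribution).
#' @param n_grid Number of points on the common time base.
#' @return List of class `frap_population`: `curve` (tibble `t`, `mean_F`,
#'   `sem_F`, `n`) and `slow_pools` (tibble `region_id`,
#'   `slow_pool_fraction`).
#' @export
population_recovery <- function(norm, fits, n_grid = 100) {
  post <- norm[norm$phase == "post" & norm$region_id %in% fits$region_id, ]
  if (nrow(post) == 0) abort("no included post-bleach trace")
  t_max <- min(tapply(post$t, post$region_id, max))
  grid <- seq(0, t_max, length.out = n_grid)
  mat <- vapply(split(post, post$region_id), function(tr) {
    approx(tr$t, tr$F, xout = grid)$y
  }, numeric(n_grid))
  mat <- matrix(mat, nrow = n_grid)
  curve <- tibble(
    t = grid,
    mean_F = rowMeans(mat),
    sem_F = apply(mat, 1, sd) / sqrt(ncol(mat)),
    n = ncol(mat)
  )
  ok <- fits$converged & !fits$degenerate
  structure(
    list(curve = curve,
         slow_pools = tibble(region_id = fits$region_id[ok],
                             slow_pool_fraction = fits$slow_pool_fraction[ok])),
    class = "frap_population"
  )
}
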