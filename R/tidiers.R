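#' Tidy a FRAP fit
#'
#' @param x A `frap_fit` from [fit_frap_trace()].
#' @param ... Unused.
#' @return Tibble with one row per model parameter (`term`, `estimate`).
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble(
    term = c("F0", "p", "tauf", "q", "taus"),
    estimate = c(x$F0, x$p, x$tauf, x$q, x$taus)
  )
}

#' Glance at a FRAP fit
#'
#' @param x A `frap_fit`.
#' @param ... Unused.
#' @return One-row tibble: `slow_pool_fraction`, `converged`,
#'   `degenerate`, `rss`, `n`.
#' @export
glance.frap_fit <- function(x, ...) {
  tibble(slow_pool_fraction = x$slow_pool_fraction, converged = x$converged,
         degenerate = x$degenerate, rss = x$rss, n = x$n)
}

#' Tidy a confinement fit
#'
#' @param x A `confinement_fit` from [fit_confinement()].
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` for `r_conf` (um), `tau` (s),
#'   `D_conf` (um^2/s).
#' @export
tidy.confinement_fit <- function(x, ...) {
  tibble(term = c("r_conf", "tau", "D_conf"),
         estimate = c(x$r_conf, x$tau, x$D_conf))
}

#' Glance at a confinement fit
#'
#' @param x A `confinement_fit`.
#' @param ... Unused.
#' @return One-row tibble: `converged`, `rss`, `n_lags`.
#' @export
glance.confinement_fit <- function(x, ...) {
  tibble(converged = x$converged, rss = x$rss, n_lags = nrow(x$window))
}

#' Tidy an exocytosis decay fit
#'
#' @param x An `exo_decay_fit` from [fit_event_decay()].
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` for `amplitude`, `decay_tau`,
#'   `offset`.
#' @export
tidy.exo_decay_fit <- function(x, ...) {
  tibble(term = c("amplitude", "decay_tau", "offset"),
         estimate = c(x$amplitude, x$decay_tau, x$offset))
}

#' Glance at an exocytosis decay fit
#'
#' @param x An `exo_decay_fit`.
#' @param ... Unused.
#' @return One-row tibble: `fit_ok`, `rss`, `n`.
#' @export
glance.exo_decay_fit <- function(x, ...) {
  tibble(fit_ok = x$fit_ok, rss = x$rss, n = x$n)
}
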