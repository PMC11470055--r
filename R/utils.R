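# internal helpers shared across modules

#' Convert micrometres to nanometres
#'
#' Trajectory analysis works in micrometres and seconds; localization-table
#' analysis works in nanometres. These converters make the unit change
#' explicit at module boundaries.
#'
#' @param x Numeric vector of lengths in micrometres.
#' @return Numeric vector in nanometres.
#' @export
#' @examples
#' um_to_nm(0.08)
um_to_nm <- function(x) x * 1000

#' Convert nanometres to micrometres
#'
#' @param x Numeric vector of lengths in nanometres.
#' @return Numeric vector in micrometres.
#' @export
nm_to_um <- function(x) x / 1000

# stop unless all named columns are present
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# positive finite scalar check
check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

# box-constrained least squares on a residual function: unconstrained
# Levenberg-Marquardt first (exact on clean data); if the optimum leaves
# the box, refine with L-BFGS-B inside it. Returns NULL on failure.
nls_lm_fit <- function(par, resid_fn, lower = NULL, upper = NULL,
                       maxiter = 500) {
  res <- tryCatch(
    minpack.lm::nls.lm(par = par, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = maxiter)),
    error = function(e) NULL
  )
  ok <- !is.null(res) && res$info %in% 1:4 && is.finite(res$deviance)
  p <- if (ok) unlist(res$par) else unlist(par)
  in_box <- (is.null(lower) || all(p >= lower - 1e-12)) &&
    (is.null(upper) || all(p <= upper + 1e-12))
  if (ok && in_box) return(list(par = p, rss = res$deviance))
  if (is.null(lower) && is.null(upper)) return(if (ok) list(par = p, rss = res$deviance) else NULL)
  # project into the box and polish with a bounded quasi-Newton pass
  p0 <- pmin(pmax(p, lower %||% -Inf), upper %||% Inf)
  obj <- function(x) {
    r <- resid_fn(setNames(x, names(p0)))
    if (!all(is.finite(r))) return(.Machine$double.xmax)
    sum(r^2)
  }
  opt <- tryCatch(
    optim(p0, obj, method = "L-BFGS-B",
          lower = lower %||% -Inf, upper = upper %||% Inf,
          control = list(maxit = maxiter)),
    error = function(e) NULL
  )
  if (is.null(opt)) return(NULL)
  list(par = setNames(opt$par, names(p0)), rss = opt$value)
}

# polygon area by the shoelace formula; vertices in order
shoelace_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# area of the convex hull of a 2D point set; 0 for degenerate hulls
convex_hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  shoelace_area(pts[h, 1], pts[h, 2])
}
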