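#' DBSCAN parameters for subsynaptic-domain segmentation
#'
#' Defaults follow the published settings for the two channels:
#' presynaptic RIM1/2 scaffolds use radius 80 nm with minPts 40,
#' postsynaptic GluA1/2 receptors use radius 70 nm with minPts 30.
#' `minPts` counts the point itself (implementations differ on this;
#' stated here explicitly).
#'
#' @param channel `"RIM"` or `"GluA"` to pick the published defaults, or
#'   `NULL` with explicit `radius`/`minPts`.
#' @param radius DBSCAN epsilon in nanometres.
#' @param minPts Minimum neighborhood size (self-inclusive) for a core
#'   point.
#' @return Object of class `dbscan_params`.
#' @export
#' @examples
#' dbscan_params("RIM")
dbscan_params <- function(channel = NULL, radius = NULL, minPts = NULL) {
  if (!is.null(channel)) {
    defaults <- list(RIM = c(80, 40), GluA = c(70, 30))
    if (!channel %in% names(defaults)) {
      abort("`channel` must be \"RIM\" or \"GluA\" (or give radius/minPts directly)")
    }
    radius <- radius %||% defaults[[channel]][1]
    minPts <- minPts %||% defaults[[channel]][2]
  }
  check_positive_scalar(radius, "radius")
  if (minPts < 1) abort("`minPts` must be at least 1")
  structure(list(channel = channel, radius = radius, minPts = as.integer(minPts)),
            class = "dbscan_params")
}

# grid-bucketed fixed-radius neighbor lists (indices, self-inclusive)
.eps_neighbors <- function(x, y, eps) {
  n <- length(x)
  cx <- floor(x / eps)
  cy <- floor(y / eps)
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)
  eps2 <- eps^2
  neighbors <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- unlist(buckets[paste(rep(cx[i] + (-1:1), 3),
                                 rep(cy[i] + (-1:1), each = 3))],
                   use.names = FALSE)
    d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
    nb <- cand[d2 <= eps2]
    neighbors[[i]] <- nb[order(nb)]
  }
  neighbors
}

#' Density-based clustering of a localization table (DBSCAN)
#'
#' Classic DBSCAN with Euclidean epsilon-neighborhoods: a point whose
#' neighborhood (including itself) holds at least `minPts` points is a
#' core point; clusters grow by core reachability; non-core points inside
#' a core neighborhood become border points of the first cluster that
#' claims them in deterministic input order; everything else is noise
#' (label 0). Cluster ids are assigned in input order, so identical input
#' yields identical labels.
#'
#' @param locs Tibble with `x_nm`, `y_nm` (single channel).
#' @param params A [dbscan_params()].
#' @return Integer vector of cluster labels (0 = noise), one per row of
#'   `locs`.
#' @export
#' @examples
#' pts <- tibble::tibble(x_nm = rnorm(60, sd = 10), y_nm = rnorm(60, sd = 10))
#' table(dbscan_cluster(pts, dbscan_params(radius = 50, minPts = 10)))
dbscan_cluster <- function(locs, params) {
  stopifnot(inherits(params, "dbscan_params"))
  check_columns(locs, c("x_nm", "y_nm"), "localization table")
  n <- nrow(locs)
  if (n == 0) return(integer(0))
  if (any(!is.finite(locs$x_nm)) || any(!is.finite(locs$y_nm))) {
    abort("localization coordinates must be finite")
  }
  neighbors <- .eps_neighbors(locs$x_nm, locs$y_nm, params$radius)
  core <- lengths(neighbors) >= params$minPts

  labels <- integer(n)
  visited <- logical(n)
  cluster <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cluster <- cluster + 1L
    visited[i] <- TRUE
    labels[i] <- cluster
    queue <- neighbors[[i]]
    in_queue <- logical(n)
    in_queue[queue] <- TRUE
    head_ptr <- 1L
    while (head_ptr <= length(queue)) {
      j <- queue[head_ptr]
      head_ptr <- head_ptr + 1L
      if (labels[j] == 0L) labels[j] <- cluster # first claim wins
      if (!visited[j]) {
        visited[j] <- TRUE
        if (core[j]) {
          nb <- neighbors[[j]]
          new <- nb[!in_queue[nb]]
          if (length(new) > 0) {
            queue <- c(queue, new)
            in_queue[new] <- TRUE
          }
        }
      }
    }
  }
  labels
}

#' Per-cluster subsynaptic-domain metrics
#'
#' For every DBSCAN cluster: the centroid (mean of member coordinates),
#' the member count, and the cluster surface measured as the area of the
#' 2D convex hull of the members. Degenerate hulls (fewer than three
#' distinct points, or collinear members) get surface 0 and a flag.
#'
#' @param locs The localization tibble passed to [dbscan_cluster()].
#' @param labels Its label vector.
#' @param channel Optional channel tag recorded on each SSD.
#' @return Tibble of class `ssd_table`: `ssd_id`, `channel`, `x_nm`,
#'   `y_nm` (centroid), `n_locs`, `surface_nm2`, `degenerate`.
#' @export
ssd_metrics <- function(locs, labels, channel = NULL) {
  check_columns(locs, c("x_nm", "y_nm"), "localization table")
  if (length(labels) != nrow(locs)) abort("`labels` must match `locs` rows")
  if (is.null(channel) && "channel" %in% names(locs) && nrow(locs) > 0) {
    channel <- locs$channel[1]
  }
  ids <- sort(unique(labels[labels > 0]))
  rows <- purrr::map(ids, function(id) {
    m <- labels == id
    area <- convex_hull_area(locs$x_nm[m], locs$y_nm[m])
    tibble(
      ssd_id = id,
      channel = channel %||% NA_character_,
      x_nm = mean(locs$x_nm[m]),
      y_nm = mean(locs$y_nm[m]),
      n_locs = sum(m),
      surface_nm2 = area,
      degenerate = area == 0
    )
  })
  out <- if (length(rows) > 0) bind_rows(rows) else {
    tibble(ssd_id = integer(), channel = character(), x_nm = double(),
           y_nm = double(), n_locs = integer(), surface_nm2 = double(),
           degenerate = logical())
  }
  class(out) <- c("ssd_table", class(out))
  out
}

#' Segment one channel into subsynaptic domains
#'
#' Convenience wrapper: [dbscan_cluster()] followed by [ssd_metrics()].
#'
#' @param locs Single-channel localization tibble (`x_nm`, `y_nm`).
#' @param params A [dbscan_params()]; defaults to the channel named in
#'   the table's `channel` column.
#' @return An `ssd_table` (see [ssd_metrics()]).
#' @export
#' @examples
#' cfg <- sim_config(1, field_size = c(3, 3))
#' sim <- simulate_localizations(cfg, nanocolumn_truth(cfg, n_synapses = 2))
#' segment_ssds(sim$rim)
segment_ssds <- function(locs, params = NULL) {
  if (is.null(params)) {
    ch <- if ("channel" %in% names(locs) && nrow(locs) > 0) locs$channel[1] else NULL
    if (is.null(ch)) abort("supply `params` or a `channel` column")
    params <- dbscan_params(ch)
  }
  ssd_metrics(locs, dbscan_cluster(locs, params))
}
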