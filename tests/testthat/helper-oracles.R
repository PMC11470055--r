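# Independent reference implementations used as oracles.

# O(n^2) double-loop MSD: average squared displacement over every pair of
# rows whose frame numbers differ by exactly k
msd_oracle <- function(traj, max_lag, dt) {
  n <- nrow(traj)
  msd <- rep(NA_real_, max_lag)
  for (k in seq_len(max_lag)) {
    acc <- c()
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (traj$frame[j] - traj$frame[i] == k) {
          acc <- c(acc, (traj$x_um[j] - traj$x_um[i])^2 +
                     (traj$y_um[j] - traj$y_um[i])^2)
        }
      }
    }
    if (length(acc) > 0) msd[k] <- mean(acc)
  }
  tibble::tibble(lag = seq_len(max_lag), lag_s = seq_len(max_lag) * dt, msd = msd)
}

# Reference DBSCAN built on a full distance matrix and igraph connected
# components of the core-point graph. Returns core flags, a canonical
# cluster id per core point, the noise set, and for every border point the
# set of admissible clusters (those owning a core point within eps).
dbscan_oracle <- function(x, y, eps, minPts) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  nb_count <- rowSums(d <= eps) # self-inclusive
  core <- nb_count >= minPts
  core_idx <- which(core)
  comp <- integer(n)
  if (length(core_idx) > 0) {
    sub <- d[core_idx, core_idx, drop = FALSE] <= eps
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected", diag = FALSE)
    comp[core_idx] <- igraph::components(g)$membership
  }
  admissible <- lapply(seq_len(n), function(i) {
    if (core[i]) return(comp[i])
    sort(unique(comp[core_idx[d[i, core_idx] <= eps]]))
  })
  list(core = core, comp = comp,
       noise = vapply(admissible, length, integer(1)) == 0 & !core,
       admissible = admissible)
}

# check a label vector from dbscan_cluster() against the oracle semantics
expect_dbscan_matches_oracle <- function(locs, labels, eps, minPts) {
  orc <- dbscan_oracle(locs$x_nm, locs$y_nm, eps, minPts)
  # noise agrees exactly
  expect_identical(labels == 0, unname(orc$noise))
  # core partition agrees up to relabeling: the map cluster id <-> component
  # must be a bijection on core points
  core <- orc$core
  if (any(core)) {
    tab <- table(labels[core], orc$comp[core])
    expect_true(all(rowSums(tab > 0) == 1))
    expect_true(all(colSums(tab > 0) == 1))
    # translate cluster labels to components and check border admissibility
    map <- apply(tab, 1, function(r) as.integer(colnames(tab)[which(r > 0)]))
    names(map) <- rownames(tab)
    border <- !core & labels > 0
    for (i in which(border)) {
      expect_true(map[[as.character(labels[i])]] %in% orc$admissible[[i]])
    }
  }
}

# independent polygon-area route for the Monte-Carlo hull oracle: fan
# triangulation from the vertex centroid using cross products
triangle_fan_area <- function(px, py) {
  h <- grDevices::chull(px, py)
  vx <- px[h]
  vy <- py[h]
  cx <- mean(vx)
  cy <- mean(vy)
  n <- length(vx)
  a <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    a <- a + abs((vx[i] - cx) * (vy[j] - cy) - (vx[j] - cx) * (vy[i] - cy)) / 2
  }
  a
}
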