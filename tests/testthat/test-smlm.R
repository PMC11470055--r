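test_that("coincident points above minPts form one cluster; sparse points are noise", {
  dense <- tibble::tibble(x_nm = rep(100, 50), y_nm = rep(100, 50))
  labels <- dbscan_cluster(dense, dbscan_params(radius = 80, minPts = 40))
  expect_equal(labels, rep(1L, 50))

  set.seed(5)
  sparse <- tibble::tibble(x_nm = runif(30, 0, 1e5), y_nm = runif(30, 0, 1e5))
  expect_equal(dbscan_cluster(sparse, dbscan_params(radius = 80, minPts = 40)),
               rep(0L, 30))
})

test_that("every localization is a member of exactly one cluster or noise", {
  set.seed(8)
  locs <- tibble::tibble(x_nm = c(rnorm(80, 0, 30), runif(40, -500, 500)),
                         y_nm = c(rnorm(80, 0, 30), runif(40, -500, 500)))
  labels <- dbscan_cluster(locs, dbscan_params(radius = 70, minPts = 30))
  expect_length(labels, nrow(locs))
  expect_true(all(labels >= 0))
})

test_that("cluster labels match the reference DBSCAN on random instances", {
  set.seed(12)
  for (rep in 1:15) {
    n_clusters <- sample(1:4, 1)
    pts <- do.call(rbind, lapply(seq_len(n_clusters), function(i) {
      c0 <- runif(2, 200, 1800)
      n <- sample(20:80, 1)
      cbind(rnorm(n, c0[1], 40), rnorm(n, c0[2], 40))
    }))
    pts <- rbind(pts, cbind(runif(60, 0, 2000), runif(60, 0, 2000)))
    locs <- tibble::tibble(x_nm = pts[, 1], y_nm = pts[, 2])
    eps <- sample(c(60, 80), 1)
    minPts <- sample(c(10, 20), 1)
    labels <- dbscan_cluster(locs, dbscan_params(radius = eps, minPts = minPts))
    expect_dbscan_matches_oracle(locs, labels, eps, minPts)
  }
})

test_that("labels are deterministic and invariant under rigid motions", {
  set.seed(9)
  locs <- tibble::tibble(x_nm = c(rnorm(60, 0, 30), rnorm(60, 400, 30)),
                         y_nm = c(rnorm(60, 0, 30), rnorm(60, 0, 30)))
  p <- dbscan_params(radius = 80, minPts = 40)
  l1 <- dbscan_cluster(locs, p)
  expect_identical(l1, dbscan_cluster(locs, p))
  # translation + rotation preserve the partition
  th <- 0.7
  rot <- tibble::tibble(
    x_nm = cos(th) * locs$x_nm - sin(th) * locs$y_nm + 1e4,
    y_nm = sin(th) * locs$x_nm + cos(th) * locs$y_nm - 5e3
  )
  l2 <- dbscan_cluster(rot, p)
  expect_identical(l1, l2)
})

test_that("SSD metrics give hull area, centroid, and degenerate flags", {
  square <- tibble::tibble(x_nm = c(0, 100, 100, 0), y_nm = c(0, 0, 100, 100))
  s <- ssd_metrics(square, rep(1L, 4), channel = "GluA")
  expect_equal(s$surface_nm2, 1e4)
  expect_equal(c(s$x_nm, s$y_nm), c(50, 50))
  expect_false(s$degenerate)

  collinear <- tibble::tibble(x_nm = c(0, 50, 100), y_nm = c(0, 0, 0))
  s2 <- ssd_metrics(collinear, rep(1L, 3))
  expect_equal(s2$surface_nm2, 0)
  expect_true(s2$degenerate)
})

test_that("hull area of Gaussian SSDs matches a Monte-Carlo oracle", {
  n <- 200
  sdv <- 35
  set.seed(77)
  oracle <- replicate(3000, {
    triangle_fan_area(rnorm(n, sd = sdv), rnorm(n, sd = sdv))
  })
  set.seed(177)
  got <- replicate(40, {
    pts <- tibble::tibble(x_nm = rnorm(n, sd = sdv), y_nm = rnorm(n, sd = sdv))
    ssd_metrics(pts, rep(1L, n))$surface_nm2
  })
  se <- sd(oracle) / sqrt(length(got))
  expect_lt(abs(mean(got) - mean(oracle)), 3 * se)
})

test_that("planted SSDs above 2x minPts are recovered at zero background", {
  cfg <- sim_config(83, field_size = c(8, 8))
  truth <- nanocolumn_truth(cfg, n_synapses = 25, locs_per_ssd = 80,
                            ssd_radius_nm = 35, background_density = 0)
  sim <- simulate_localizations(cfg, truth)
  rim_ssds <- segment_ssds(sim$rim)
  glua_ssds <- segment_ssds(sim$glua)
  expect_gte(nrow(rim_ssds), ceiling(0.95 * 25))
  expect_gte(nrow(glua_ssds), ceiling(0.95 * 25))
})

test_that("SSDs below minPts are not detected", {
  cfg <- sim_config(89, field_size = c(6, 6))
  truth <- nanocolumn_truth(cfg, n_synapses = 8, locs_per_ssd = 15,
                            background_density = 0)
  sim <- simulate_localizations(cfg, truth)
  expect_equal(nrow(segment_ssds(sim$rim)), 0) # minPts 40 vs ~15 locs
})

test_that("synapse regions cover planted synapses and empty intersections warn", {
  cfg <- sim_config(97, field_size = c(4, 4))
  truth <- nanocolumn_truth(cfg, n_synapses = 2, locs_per_ssd = 120)
  sim <- simulate_localizations(cfg, truth)
  regions <- build_synapse_regions(sim$rim, sim$glua)
  expect_gte(regions$n_regions, 1)
  rid_rim <- nanosyn:::region_at(regions, truth$rim_x_nm, truth$rim_y_nm)
  rid_glua <- nanosyn:::region_at(regions, truth$glua_x_nm, truth$glua_y_nm)
  expect_true(all(rid_rim > 0))
  expect_true(all(rid_glua > 0))

  # channels confined to disjoint halves cannot intersect
  left <- tibble::tibble(x_nm = runif(300, 0, 1500), y_nm = runif(300, 0, 4000))
  right <- tibble::tibble(x_nm = runif(300, 2500, 4000), y_nm = runif(300, 0, 4000))
  expect_warning(empty <- build_synapse_regions(left, right), "intersect")
  expect_equal(empty$n_regions, 0)
})

test_that("a user-supplied mask bypasses rendering", {
  m <- matrix(0, 10, 10)
  m[2:4, 2:4] <- 1
  m[7:9, 7:9] <- 1
  regions <- build_synapse_regions(mask = m, render_px = 100)
  expect_equal(regions$n_regions, 2)
  expect_equal(regions$provenance, "user")
})

test_that("SSD counts per synapse recover the planted layout exactly", {
  cfg <- sim_config(101, field_size = c(8, 8))
  truth <- nanocolumn_truth(cfg, n_synapses = 9, ssd_pairs_per_synapse = 2,
                            locs_per_ssd = 100, background_density = 0)
  sim <- simulate_localizations(cfg, truth)
  rim_ssds <- segment_ssds(sim$rim)
  glua_ssds <- segment_ssds(sim$glua)
  regions <- build_synapse_regions(sim$rim, sim$glua)
  res <- assign_and_count(dplyr::bind_rows(rim_ssds, glua_ssds), regions)
  expect_equal(regions$n_regions, 9)
  expect_true(all(res$counts$n_ssd == 2))
  expect_true(all(!is.na(res$ssds$synapse_id)))
})

test_that("pairing takes the nearest scaffold SSD within 350 nm", {
  glua <- tibble::tibble(ssd_id = 1L, x_nm = 0, y_nm = 0)
  rim <- tibble::tibble(ssd_id = 1:2, x_nm = c(50, 200), y_nm = 0)
  pr <- pair_nanocolumns(glua, rim)
  expect_equal(pr$rim_ssd_id, 1L)
  expect_equal(pr$distance_nm, 50)
  far <- tibble::tibble(ssd_id = 1L, x_nm = 400, y_nm = 0)
  pr2 <- pair_nanocolumns(glua, far)
  expect_false(pr2$paired)
  expect_true(is.na(pr2$rim_ssd_id))
  none <- pair_nanocolumns(glua, rim[0, ])
  expect_false(none$paired)
})

test_that("pairing is a function of centroids only", {
  set.seed(31)
  glua <- tibble::tibble(ssd_id = 1:5, x_nm = runif(5, 0, 2000),
                         y_nm = runif(5, 0, 2000), n_locs = 50L,
                         surface_nm2 = 1e4)
  rim <- tibble::tibble(ssd_id = 1:5, x_nm = glua$x_nm + 60, y_nm = glua$y_nm,
                        n_locs = 60L, surface_nm2 = 1.2e4)
  p1 <- pair_nanocolumns(glua, rim)
  # perturb every non-centroid column
  glua2 <- glua
  glua2$n_locs <- glua2$n_locs + 17L
  glua2$surface_nm2 <- glua2$surface_nm2 * 3
  p2 <- pair_nanocolumns(glua2, rim)
  expect_equal(p1$rim_ssd_id, p2$rim_ssd_id)
  expect_equal(p1$distance_nm, p2$distance_nm)
})

test_that("planted 60 nm offsets are recovered within the Monte-Carlo bound", {
  cfg <- sim_config(103, field_size = c(10, 10))
  truth <- nanocolumn_truth(cfg, n_synapses = 50, offset_nm = 60,
                            locs_per_ssd = 100, ssd_radius_nm = 35,
                            background_density = 0)
  sim <- simulate_localizations(cfg, truth)
  pr <- pair_nanocolumns(segment_ssds(sim$glua), segment_ssds(sim$rim))
  got <- mean(pr$distance_nm[pr$paired])
  # Monte-Carlo oracle: distance between two centroids at true offset 60,
  # each averaged over Poisson(100) points with per-axis sd 17.5
  set.seed(204)
  mc <- replicate(4000, {
    n1 <- max(rpois(1, 100), 2)
    n2 <- max(rpois(1, 100), 2)
    dx <- 60 + rnorm(1, sd = 17.5 / sqrt(n1)) - rnorm(1, sd = 17.5 / sqrt(n2))
    dy <- rnorm(1, sd = 17.5 / sqrt(n1)) - rnorm(1, sd = 17.5 / sqrt(n2))
    sqrt(dx^2 + dy^2)
  })
  se <- sd(mc) / sqrt(sum(pr$paired))
  expect_lt(abs(got - mean(mc)), 3 * se + 0.5)
})

test_that("the distance histogram is a relative-frequency distribution", {
  pr <- structure(
    tibble::tibble(glua_ssd_id = 1:4, rim_ssd_id = 1:4,
                   distance_nm = c(15, 25, 45, 330), paired = TRUE),
    class = c("nanocolumn_pairing", class(tibble::tibble()))
  )
  h <- pairing_histogram(pr, bin_width = 20)
  expect_equal(sum(h$rel_freq), 1)
  expect_equal(h$count[h$bin_mid == 10], 1L)
})
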