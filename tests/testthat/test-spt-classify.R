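test_that("auto immobility threshold follows the resolution formula", {
  expect_identical(spt_config()$D_threshold, 0.04^2 / (4 * 4 * 0.02))
  cfg <- spt_config(resolution = 0.05, n_fit_points = 5, dt = 0.01)
  expect_identical(cfg$D_threshold, 0.05^2 / (4 * 5 * 0.01))
})

test_that("planted motion classes are recovered on synthetic populations", {
  cfg <- sim_config(31)
  scfg <- spt_config()
  sim <- simulate_trajectories(
    cfg, n_per_class = c(brownian = 120, confined = 120, immobile = 120),
    D = c(brownian = 0.2, confined = 0.1, immobile = 0), r_conf = 0.1
  )
  reports <- classify_tracks(sim$tracks, scfg)
  merged <- dplyr::left_join(reports, sim$truth, by = "track_id")
  acc <- tapply(
    merged$motion_class == c(brownian = "diffusive", confined = "confined",
                             immobile = "immobile")[merged$motion_model],
    merged$motion_model, mean
  )
  expect_gte(acc[["brownian"]], 0.8)
  expect_gte(acc[["confined"]], 0.8)
  expect_gte(acc[["immobile"]], 0.8)
  # D_diff present exactly for diffusive tracks
  expect_true(all(is.na(reports$D_diff[reports$motion_class != "diffusive"])))
  expect_true(all(!is.na(reports$D_diff[reports$motion_class == "diffusive"])))
})

test_that("tracks shorter than min_points never reach the reports", {
  cfg <- sim_config(37)
  sim <- simulate_trajectories(cfg, n_per_class = c(brownian = 30),
                               track_length = c(5, 20))
  reports <- classify_tracks(sim$tracks, spt_config())
  short <- sim$truth$track_id[sim$truth$n_points < 10]
  expect_length(intersect(reports$track_id, short), 0)
  expect_true(all(reports$n_points >= 10))
})

test_that("immobile fraction is monotone in the threshold sweep", {
  cfg <- sim_config(41)
  sim <- simulate_trajectories(cfg, n_per_class = c(brownian = 60, immobile = 60))
  fracs <- vapply(c(0.001, 0.005, 0.02, 0.1), function(thr) {
    rep <- classify_tracks(sim$tracks, spt_config(D_threshold = thr))
    mean(rep$motion_class == "immobile")
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("synaptic sorting applies the >50% rule and dwell = frames * dt", {
  m <- synapse_mask(c(2, 2), centers = cbind(0.5, 0.5), radius_um = 0.4)
  cfg <- spt_config()
  all_in <- tibble::tibble(frame = 1:25, x_um = 0.5, y_um = 0.5)
  res <- assign_synaptic(all_in, m, cfg)
  expect_true(res$is_synaptic)
  expect_equal(res$dwell_time_s, 0.5)

  mixed <- tibble::tibble(frame = 1:25,
                          x_um = c(rep(0.5, 10), rep(1.7, 15)), y_um = 0.5)
  res2 <- assign_synaptic(mixed, m, cfg)
  expect_false(res2$is_synaptic) # 40% inside
  expect_equal(res2$dwell_time_s, 0.2)
  expect_equal(res2$visits$n_frames, 10L)

  # exactly half inside is non-synaptic (strict >)
  half <- tibble::tibble(frame = 1:20,
                         x_um = c(rep(0.5, 10), rep(1.7, 10)), y_um = 0.5)
  expect_false(assign_synaptic(half, m, cfg)$is_synaptic)
})

test_that("inside fraction equals a brute-force per-frame tally", {
  cfg <- sim_config(43)
  m <- synapse_mask(cfg$field_size,
                    centers = cbind(runif(5, 2, 8), runif(5, 2, 8)),
                    radius_um = 0.5)
  sim <- simulate_trajectories(cfg, n_per_class = c(brownian = 20),
                               masks = m)
  for (tr in split(sim$tracks, sim$tracks$track_id)) {
    res <- assign_synaptic(tr, m, spt_config())
    manual <- vapply(seq_len(nrow(tr)), function(i) {
      r <- floor(tr$y_um[i] / m$pixel_size_um) + 1
      c <- floor(tr$x_um[i] / m$pixel_size_um) + 1
      r >= 1 && r <= nrow(m$mask) && c >= 1 && c <= ncol(m$mask) &&
        m$mask[r, c] > 0
    }, logical(1))
    expect_equal(res$inside_fraction, mean(manual))
  }
})

test_that("off-raster coordinates count as outside and are tallied", {
  m <- synapse_mask(c(1, 1), centers = cbind(0.5, 0.5), radius_um = 0.6)
  traj <- tibble::tibble(frame = 1:10,
                         x_um = c(rep(0.5, 6), rep(5, 4)), y_um = 0.5)
  res <- assign_synaptic(traj, m, spt_config())
  expect_equal(res$n_outside_raster, 4L)
  expect_equal(res$inside_fraction, 0.6)
})

test_that("population fractions sum to one and are order-invariant", {
  cfg <- sim_config(47)
  sim <- simulate_trajectories(cfg, n_per_class = c(brownian = 40, confined = 30,
                                                    immobile = 30))
  reports <- classify_tracks(sim$tracks, spt_config())
  s <- summarize_population(reports)
  expect_equal(s$frac_immobile + s$frac_confined + s$frac_diffusive, 1,
               tolerance = 1e-12)
  shuffled <- reports[sample(nrow(reports)), ]
  s2 <- summarize_population(shuffled)
  expect_equal(s[c("frac_immobile", "frac_confined", "frac_diffusive")],
               s2[c("frac_immobile", "frac_confined", "frac_diffusive")])
})

test_that("an all-immobile population reports fractions (1, 0, 0)", {
  cfg <- sim_config(53, loc_noise_sd = 0.01)
  sim <- simulate_trajectories(cfg, n_per_class = c(immobile = 25))
  s <- summarize_population(classify_tracks(sim$tracks, spt_config()))
  expect_equal(c(s$frac_immobile, s$frac_confined, s$frac_diffusive), c(1, 0, 0))
})

test_that("empty report tables are rejected", {
  expect_error(summarize_population(tibble::tibble()), "empty")
})
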