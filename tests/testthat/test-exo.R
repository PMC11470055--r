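test_that("a planted bright event is detected at its position and onset", {
  truth <- exo_truth(x_px = 40, y_px = 60, onset_frame = 25, amplitude = 30,
                     decay_tau = 6, noise_sd = 3) # amplitude 10x noise
  sim <- simulate_exo_movie(sim_config(7), truth, frame_count = 80,
                            width = 96, height = 96)
  ev <- detect_events(sim$movie, dt = sim$dt)
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev$x_px - 40), 2)
  expect_lte(abs(ev$y_px - 60), 2)
  expect_lte(abs(ev$onset_frame - 25), 1)
})

test_that("pure-noise movies yield zero detections on nearly all seeds", {
  hits <- vapply(1:12, function(s) {
    sim <- simulate_exo_movie(sim_config(s), exo_truth(noise_sd = 2),
                              frame_count = 100, width = 96, height = 96)
    nrow(detect_events(sim$movie))
  }, integer(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("well-separated simultaneous events are counted individually", {
  truth <- exo_truth(x_px = c(30, 80), y_px = c(48, 48), onset_frame = c(20, 20),
                     amplitude = c(40, 40), decay_tau = 6, noise_sd = 3)
  sim <- simulate_exo_movie(sim_config(3), truth, frame_count = 60,
                            width = 112, height = 96)
  expect_equal(nrow(detect_events(sim$movie)), 2)
})

test_that("detection count equals truth for strong, separated events", {
  correct <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    n <- sample(2:4, 1)
    truth <- exo_truth(
      x_px = seq(20, 100, length.out = n) + runif(n, -3, 3),
      y_px = runif(n, 20, 100),
      onset_frame = sample(seq(16, 80, by = 8), n),
      amplitude = rep(25, n), decay_tau = 5, noise_sd = 2.5 # 10 sigma
    )
    sim <- simulate_exo_movie(sim_config(500 + s), truth, frame_count = 100,
                              width = 120, height = 120)
    nrow(detect_events(sim$movie)) == n
  }, logical(1))
  expect_gte(mean(correct), 0.9)
})

test_that("noiseless decay fits recover tau almost exactly", {
  t <- seq(0, 30, by = 0.5)
  fit <- fit_event_decay(tibble::tibble(t = t, intensity = 100 * exp(-t / 2)))
  expect_true(fit$fit_ok)
  expect_lt(abs(fit$decay_tau - 2) / 2, 1e-6)
  expect_lt(abs(fit$amplitude - 100) / 100, 1e-6)
})

test_that("decay tau survives realistic noise through the full pipeline", {
  taus <- vapply(1:12, function(s) {
    truth <- exo_truth(x_px = 48, y_px = 48, onset_frame = 15, amplitude = 40,
                       decay_tau = 8, noise_sd = 2)
    sim <- simulate_exo_movie(sim_config(700 + s), truth, frame_count = 60,
                              width = 96, height = 96)
    ev <- detect_events(sim$movie, dt = sim$dt)
    if (nrow(ev) != 1) return(NA_real_)
    fit_event_decay(ev$trace[[1]])$decay_tau
  }, numeric(1))
  expect_true(all(!is.na(taus)))
  expect_lt(abs(median(taus) - 8) / 8, 0.1)
})

test_that("constant traces cannot be fitted", {
  fit <- fit_event_decay(tibble::tibble(t = 0:20, intensity = rep(5, 21)))
  expect_false(fit$fit_ok)
})

test_that("event frequency is count over area times duration", {
  f <- event_frequency(6, cell_area_um2 = 100, duration_s = 60)
  expect_equal(f$frequency, 1e-3)
  f2 <- event_frequency(6, cell_area_um2 = 100, duration_s = 120)
  expect_equal(f2$frequency, f$frequency / 2)
  expect_error(event_frequency(6, 0, 60), "cell_area_um2")
})

test_that("frequency estimation is consistent with Poisson planting", {
  lambda <- 4 # expected events per movie
  area <- 96 * 96 * 0.1^2
  duration <- 100 * 2
  set.seed(900)
  counts <- vapply(1:10, function(s) {
    n <- rpois(1, lambda)
    if (n == 0) return(0L)
    truth <- exo_truth(x_px = runif(n, 15, 80), y_px = runif(n, 15, 80),
                       onset_frame = sample(seq(16, 90, by = 5), n),
                       amplitude = rep(30, n), decay_tau = 6, noise_sd = 2)
    sim <- simulate_exo_movie(sim_config(900 + s), truth, frame_count = 100,
                              width = 96, height = 96)
    nrow(detect_events(sim$movie))
  }, integer(1))
  est <- mean(counts) / (area * duration)
  truth_rate <- lambda / (area * duration)
  # Poisson 95% band on the mean of 10 movies
  se <- sqrt(lambda / 10) / (area * duration)
  expect_lt(abs(est - truth_rate), 3 * se)
})

test_that("degenerate inputs are rejected", {
  expect_error(detect_events(array(0, c(16, 16, 5))), "baseline")
  expect_error(
    simulate_exo_movie(sim_config(1),
                       exo_truth(x_px = 200, y_px = 10, onset_frame = 5,
                                 amplitude = 10, decay_tau = 1),
                       frame_count = 20, width = 64, height = 64),
    "outside the field"
  )
  expect_error(
    simulate_exo_movie(sim_config(1),
                       exo_truth(x_px = 10, y_px = 10, onset_frame = 50,
                                 amplitude = 10, decay_tau = 1),
                       frame_count = 20, width = 64, height = 64),
    "within the movie"
  )
})
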