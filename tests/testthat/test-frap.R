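test_that("normalization sends the pre-bleach mean to 1 and first post frame to 0", {
  sim <- simulate_frap_traces(sim_config(3), frap_truth(2, noise_sd = 0))
  norm <- normalize_frap(sim)
  for (tr in split(norm, norm$region_id)) {
    expect_equal(mean(tr$F[tr$phase == "pre"]), 1, tolerance = 1e-9)
    expect_equal(tr$F[tr$frame == 11], 0, tolerance = 1e-9)
  }
})

test_that("bleach correction inverts acquisition photobleaching", {
  truth <- frap_truth(1, noise_sd = 0, p = 0.5, q = 0.3, tauf = 5, taus = 120)
  sim <- simulate_frap_traces(sim_config(3), truth, n_post = 600,
                              acquisition_bleach_rate = 0.002)
  norm <- normalize_frap(sim)
  # late plateau of the normalized trace approaches p + q
  late <- norm$F[norm$t > 500]
  model_late <- 0.5 * (1 - exp(-550 / 5)) + 0.3 * (1 - exp(-550 / 120))
  expect_lt(abs(mean(late) - model_late) / model_late, 0.02)
})

test_that("normalizing an already-normalized trace is the identity", {
  t <- 0:100
  f <- 0.6 * (1 - exp(-pmax(t - 10, 0) / 20))
  raw <- tibble::tibble(
    region_id = 1, frame = t + 1,
    roi_intensity = c(rep(1, 10), f[11:101]),
    bg_intensity = 0, ref_intensity = 1
  )
  norm <- normalize_frap(raw, bleach_frame = 11)
  expect_equal(norm$F, raw$roi_intensity, tolerance = 1e-12)
})

test_that("quality control applies the depth and negativity rules", {
  mk <- function(depth, dip = 0) {
    f <- c(rep(1000, 10), 1000 * (1 - depth) + seq(0, 300, length.out = 40))
    if (dip != 0) f[15] <- 1000 * (1 - depth) - dip * 1000
    tibble::tibble(region_id = 1, frame = seq_along(f), roi_intensity = f,
                   bg_intensity = 0, ref_intensity = 1000)
  }
  qc60 <- frap_qc(normalize_frap(mk(0.6), bleach_frame = 11))
  expect_equal(qc60$qc, "included")
  qc40 <- frap_qc(normalize_frap(mk(0.4), bleach_frame = 11))
  expect_equal(qc40$qc, "excluded_depth")
  # a post-bleach normalized value of about -0.1 trips the negativity rule
  qcneg <- frap_qc(normalize_frap(mk(0.6, dip = 0.08), bleach_frame = 11))
  expect_equal(qcneg$qc, "excluded_negative")
})

test_that("lowering the depth cut never excludes a previously included region", {
  sim <- simulate_frap_traces(sim_config(9),
                              frap_truth(12, bleach_depth = seq(0.3, 0.95, length.out = 12),
                                         noise_sd = 3))
  norm <- normalize_frap(sim)
  qc_hi <- frap_qc(norm, min_depth = 0.6)
  qc_lo <- frap_qc(norm, min_depth = 0.4)
  included_hi <- qc_hi$region_id[qc_hi$qc == "included"]
  included_lo <- qc_lo$region_id[qc_lo$qc == "included"]
  expect_true(all(included_hi %in% included_lo))
})

test_that("the double-exponential fit round-trips noiseless parameters", {
  t <- seq(0, 745, by = 5)
  truth <- list(F0 = 0, p = 0.5, tauf = 5, q = 0.3, taus = 120)
  y <- truth$p * (1 - exp(-t / truth$tauf)) + truth$q * (1 - exp(-t / truth$taus))
  fit <- fit_frap_trace(t, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$p - 0.5), 1e-3)
  expect_lt(abs(fit$q - 0.3), 1e-3)
  expect_lt(abs(fit$tauf - 5) / 5, 1e-3)
  expect_lt(abs(fit$taus - 120) / 120, 1e-3)
  expect_lt(fit$F0, 1e-3)
  expect_equal(fit$slow_pool_fraction, fit$q)
  expect_lt(fit$tauf, fit$taus)
})

test_that("a flat zero trace is flagged degenerate with empty pools", {
  fit <- fit_frap_trace(seq(0, 100, by = 2), rep(0, 51))
  expect_true(fit$degenerate)
  expect_equal(fit$p, 0)
  expect_equal(fit$q, 0)
})

test_that("mean fitted slow pool tracks the truth on a noisy cohort", {
  cfg <- sim_config(15)
  sim <- simulate_frap_traces(cfg, frap_truth(30, noise_sd = 0), n_post = 400,
                              pre_level = 1, background = 0)
  # inject sigma = 0.03 noise on the normalized scale
  norm <- normalize_frap(sim)
  set.seed(99)
  norm$F <- norm$F + rnorm(nrow(norm), sd = 0.03)
  fits <- fit_frap(norm, frap_qc(norm, negative_tol = Inf))
  expect_lt(abs(mean(fits$q) - 0.3), 0.05)
})

test_that("surface intensity is the background-subtracted first frame", {
  raw <- tibble::tibble(region_id = c(1, 1, 2, 2), frame = c(1, 2, 1, 2),
                        roi_intensity = c(500, 400, 90, 80),
                        bg_intensity = 100, ref_intensity = 1000)
  expect_warning(si <- surface_intensity(raw), "negative")
  expect_equal(si$surface_intensity, c(400, -10))
})

test_that("population curve averages traces and reports sem", {
  sim <- simulate_frap_traces(sim_config(21), frap_truth(4, noise_sd = 0))
  norm <- normalize_frap(sim)
  fits <- fit_frap(norm)
  pop <- population_recovery(norm, fits)
  expect_equal(pop$curve$sem_F, rep(0, nrow(pop$curve)), tolerance = 1e-9)
  # two distinct traces: mean equals the hand average
  two <- simulate_frap_traces(sim_config(22),
                              frap_truth(2, q = c(0.2, 0.4), noise_sd = 0))
  n2 <- normalize_frap(two)
  pop2 <- population_recovery(n2, fit_frap(n2))
  tr <- split(n2[n2$phase == "post", ], n2$region_id[n2$phase == "post"])
  hand <- (tr[[1]]$F + tr[[2]]$F) / 2
  byhand <- approx(tr[[1]]$t, hand, xout = pop2$curve$t)$y
  expect_equal(pop2$curve$mean_F, byhand, tolerance = 1e-9)
})

test_that("tidiers expose parameters and diagnostics", {
  t <- seq(0, 300, by = 2)
  fit <- fit_frap_trace(t, 0.5 * (1 - exp(-t / 5)) + 0.3 * (1 - exp(-t / 60)))
  td <- generics::tidy(fit)
  expect_equal(td$term, c("F0", "p", "tauf", "q", "taus"))
  gl <- generics::glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$slow_pool_fraction, fit$q)
})
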