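test_that("volume generation is bit-identical under a fixed seed", {
  p <- volume_params(shape = c(4, 96, 96), n_somata = 3, rng_seed = 21)
  v1 <- simulate_volume(p)
  v2 <- simulate_volume(p)
  expect_identical(v1$stack$voxels, v2$stack$voxels)
  expect_identical(v1$truth$somata, v2$truth$somata)
  v3 <- simulate_volume(volume_params(shape = c(4, 96, 96), n_somata = 3,
                                      rng_seed = 22))
  expect_false(identical(v1$stack$voxels, v3$stack$voxels))
})

test_that("a noise-free soma is recovered on the planes it dominates", {
  p <- volume_params(shape = c(7, 80, 80), n_somata = 1, noise_sd = 0,
                     soma_radius_range = c(10, 10), attenuation_length = 1e6,
                     rng_seed = 23)
  sim <- simulate_volume(p)
  tr <- sim$truth$somata
  for (z in seq_len(7)) {
    dz <- (z - tr$z) * 2.5 / 0.994
    rp <- sqrt(max(tr$r_px^2 - dz^2, 0))
    if (rp < 6) next # below the detector search range
    det <- detect_circles(sim$stack$voxels[z, , ])
    expect_equal(nrow(det), 1L)
    expect_lt((det$y - tr$y)^2 + (det$x - tr$x)^2, 2)
    expect_lte(abs(det$r - rp), 1)
  }
})

test_that("log-linear fit of the bright signal recovers the attenuation length", {
  ell <- 250
  p <- volume_params(shape = c(10, 192, 192), n_somata = 60, noise_sd = 0,
                     background = 10, attenuation_length = ell,
                     non_overlapping = FALSE, rng_seed = 24)
  sim <- simulate_volume(p)
  prof <- depth_profiles(sim$stack)
  expect_true(all(diff(prof$bright_signal) < 0))
  fit <- lm(log(bright_signal - 10) ~ depth_um, data = prof)
  expect_equal(-1 / coef(fit)[["depth_um"]], ell, tolerance = 0.02)
})

test_that("infeasible non-overlapping placement errors out", {
  expect_error(
    simulate_volume(volume_params(shape = c(2, 64, 64), n_somata = 50,
                                  rng_seed = 1)),
    class = "deepcalseq_invalid")
})

test_that("session generation is bit-identical under a fixed seed", {
  p <- session_params(n_neurons = 10, n_trials = 5, rng_seed = 25)
  s1 <- simulate_session(p)
  s2 <- simulate_session(p)
  expect_identical(s1$traces$values, s2$traces$values)
  expect_identical(s1$events$lick_times, s2$events$lick_times)
  expect_identical(s1$truth$neurons, s2$truth$neurons)
})

test_that("noise-free tuned sessions place peaks at the planted times", {
  p <- session_params(n_neurons = 30, n_trials = 10, sigma_t = 0,
                      noise_sd = 0, drift_amplitude = 0, drift_linear = 0,
                      rng_seed = 26)
  sim <- simulate_session(p)
  tensor <- align_trials(percentile_detrend(block_average(sim$traces)),
                         sim$events)
  avg <- trial_average(tensor)
  err <- avg$peak_time - sim$truth$neurons$preferred_time
  expect_true(all(abs(err) <= 0.1 + 1e-9)) # within one 10 Hz frame
})

test_that("the planted pre-reward composition is exact by construction", {
  p <- session_params(n_neurons = 100, rng_seed = 27)
  sim <- simulate_session(p)
  pre <- sim$truth$neurons$preferred_time < 0
  expect_equal(sum(pre, na.rm = TRUE), 30)
  expect_equal(sum(sim$truth$neurons$tuned), 100)
})

test_that("untuned sessions plant one uniform bump per trial", {
  p <- session_params(n_neurons = 40, n_trials = 20, fraction_tuned = 0,
                      rng_seed = 28)
  sim <- simulate_session(p)
  expect_true(all(!sim$truth$neurons$tuned))
  rel <- sim$truth$events$bump_time - sim$truth$events$delivery_time
  expect_true(all(rel >= -10 & rel < 10))
  expect_gt(ks.test(rel, "punif", -10, 10)$p.value, 0.01)
})

test_that("missed deliveries occur at the configured probability", {
  p <- session_params(n_neurons = 2, n_trials = 200,
                      miss_probability = 0.3, spontaneous_lick_rate = 0,
                      rng_seed = 29)
  sim <- simulate_session(p)
  rr <- response_rate(sim$events)
  expect_equal(rr, 0.7, tolerance = 0.1)
})

test_that("noise degrades circle-detection recall monotonically on average", {
  recall_at <- function(noise) {
    mean(vapply(1:3, function(s) {
      pl <- simulate_disc_plane(n_discs = 12, shape = c(192, 192),
                                intensity = 100, noise_sd = noise,
                                rng_seed = 100 + s)
      match_detections(detect_circles(pl$plane), pl$truth)$recall
    }, numeric(1)))
  }
  r <- vapply(c(0, 40, 90), recall_at, numeric(1))
  expect_true(all(diff(r) <= 0))
  expect_equal(r[1], 1)
})
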