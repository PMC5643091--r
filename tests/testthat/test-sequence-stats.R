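test_that("ridge-to-background handles flat and constructed traces", {
  # flat positive trace: every window mean equals the background -> ratio 1,
  # but a perfectly constant trace has no defined peak, so perturb one frame
  vals <- array(1, dim = c(1, 2, 200))
  expect_true(ridge_to_background(trial_average(make_tensor(vals)))$degenerate)

  # 12 consecutive frames = 2 (peak in the middle), remaining 188 = 1
  x <- rep(1, 200)
  x[95:106] <- 2
  x[101] <- 2 + 1e-9 # unique peak; ridge window 95..106 covers the block
  vals2 <- aperm(array(rep(x, 2), dim = c(200, 2, 1)), c(3, 2, 1))
  st <- ridge_to_background(trial_average(make_tensor(vals2)))
  expect_equal(st$ratio, 2, tolerance = 1e-6)
  expect_equal(st$ridge_dff, 2, tolerance = 1e-6)
  expect_equal(st$background_dff, 1)
})

test_that("ridge statistics agree with a frame-enumeration oracle", {
  set.seed(31)
  for (i in 1:10) {
    f <- sample(50:200, 1)
    x <- abs(rnorm(f, 1, 0.5))
    vals <- aperm(array(rep(x, 2), dim = c(f, 2, 1)), c(3, 2, 1))
    tn <- make_tensor(vals, frame_rate = f / 20)
    st <- ridge_to_background(trial_average(tn), ridge_frames = 12)
    # oracle: enumerate window membership frame by frame
    p <- which.max(x)
    lo <- min(max(p - 6, 1), f - 11)
    inridge <- seq_len(f) >= lo & seq_len(f) <= lo + 11
    expect_identical(st$ridge_dff, mean(x[inridge]))
    expect_identical(st$background_dff, mean(x[!inridge]))
    expect_identical(st$ratio, mean(x[inridge]) / mean(x[!inridge]))
  }
})

test_that("ridge ratio transforms affinely and is scale-invariant at zero offset", {
  set.seed(77)
  mk <- function(v) make_tensor(aperm(array(rep(v, 2),
                                            dim = c(length(v), 2, 1)),
                                      c(3, 2, 1)))
  for (i in 1:5) {
    x <- abs(rnorm(200, 1, 0.3))
    st <- ridge_to_background(trial_average(mk(x)))
    s <- runif(1, 0.5, 3); c0 <- runif(1, 0.1, 2)
    st2 <- ridge_to_background(trial_average(mk(s * x + c0)))
    # shifted+scaled trace: ratio becomes (ridge*s + c) / (background*s + c)
    expect_equal(st2$ratio,
                 (st$ridge_dff * s + c0) / (st$background_dff * s + c0),
                 tolerance = 1e-10)
    # and is exactly invariant when c = 0
    st3 <- ridge_to_background(trial_average(mk(s * x)))
    expect_equal(st3$ratio, st$ratio, tolerance = 1e-12)
  }
})

test_that("non-positive background is flagged as degenerate", {
  x <- c(rep(-0.1, 188), rep(2, 12))
  tn <- make_tensor(aperm(array(rep(x, 2), dim = c(200, 2, 1)), c(3, 2, 1)))
  st <- ridge_to_background(trial_average(tn))
  expect_true(st$degenerate)
  expect_true(is.na(st$ratio))
})

test_that("circular shuffle preserves per-trial value multisets and is seeded", {
  tn <- make_tuned_tensor(n_neurons = 8, n_trials = 6, noise_sd = 0.1,
                          seed = 3)
  sh <- circular_shuffle(tn, rng_seed = 42)
  # zero shifts reproduce the original average exactly
  z <- circular_shuffle(tn, shifts = matrix(0L, 8, 6))
  expect_equal(z$avg$traces, trial_average(tn)$traces)
  # determinism
  sh2 <- circular_shuffle(tn, rng_seed = 42)
  expect_identical(sh$avg$traces, sh2$avg$traces)
  expect_identical(sh$shifts, sh2$shifts)
  # multiset preservation per neuron-trial (reconstruct shifted trials)
  f <- dim(tn$values)[3]
  for (i in c(1, 5)) for (j in c(2, 6)) {
    s <- sh$shifts[i, j]
    orig <- tn$values[i, j, ]
    shifted <- orig[((seq_len(f) - 1 + s) %% f) + 1]
    expect_identical(sort(shifted), sort(orig))
  }
  # constant trials: shuffling changes nothing
  ct <- make_tensor(array(3, dim = c(2, 4, 100)))
  cs <- circular_shuffle(ct, rng_seed = 1)
  expect_true(all(cs$avg$traces == 3))
  expect_true(all(cs$stats$degenerate))
})

test_that("shuffling erodes the ridge of a strongly tuned population", {
  tn <- make_tuned_tensor(n_neurons = 40, n_trials = 20, jitter_sd = 0.3,
                          noise_sd = 0.05, seed = 6)
  st <- sequence_test(tn, rng_seed = 9)
  expect_gt(mean(st$original$ratio, na.rm = TRUE),
            mean(st$shuffled$ratio, na.rm = TRUE))
  expect_lt(st$p_value, 1e-3)
})

test_that("a tensor compared against an identity shuffle gives p near 1", {
  tn <- make_tuned_tensor(n_neurons = 20, n_trials = 10, noise_sd = 0.05,
                          seed = 8)
  d <- dim(tn$values)
  st <- sequence_test(tn, shifts = matrix(0L, d[1], d[2]))
  expect_gt(st$p_value, 0.9)
})

test_that("sequence test refuses degenerate populations", {
  ct <- make_tensor(array(1, dim = c(3, 4, 100)))
  expect_error(sequence_test(ct, rng_seed = 1),
               class = "deepcalseq_insufficient")
})

test_that("peak-time histogram uses half-open 0.5 s bins that conserve counts", {
  stats <- tibble::tibble(peak_time = rep(-3.1, 7))
  h <- peak_time_histogram(stats)
  expect_equal(nrow(h), 40L)
  expect_equal(h$count[h$bin_start == -3.5], 7L)
  expect_equal(sum(h$count), 7L)

  set.seed(12)
  stats2 <- tibble::tibble(peak_time = runif(500, -10, 10))
  h2 <- peak_time_histogram(stats2)
  expect_equal(sum(h2$count), 500L)
  expect_true(all(h2$count > 0)) # roughly flat: no empty bin at n = 500
  # boundary values land in the left-closed bin
  h3 <- peak_time_histogram(tibble::tibble(peak_time = c(-10, 0, 9.99)))
  expect_equal(h3$count[h3$bin_start == -10], 1L)
  expect_equal(h3$count[h3$bin_start == 0], 1L)
})

test_that("peak fractions respect totality and partition additivity", {
  set.seed(14)
  stats <- tibble::tibble(peak_time = runif(200, -10, 10))
  expect_equal(peak_fraction_in_interval(stats, c(-10, 10)), 1)
  parts <- sapply(seq(-10, 5, by = 5), function(a)
    peak_fraction_in_interval(stats, c(a, a + 5)))
  expect_equal(sum(parts), 1)
})

test_that("the full-length pre-reward window analysis reduces to sequence_test", {
  tn <- make_tuned_tensor(n_neurons = 30, n_trials = 10, jitter_sd = 0.5,
                          noise_sd = 0.1, seed = 5)
  wa <- window_ridge_analysis(tn, window_len = 10, rng_seed = 77)
  expect_equal(nrow(wa), 1L)
  stats <- ridge_to_background(trial_average(tn))
  pre <- which(!is.na(stats$peak_time) & stats$peak_time >= -10 &
                 stats$peak_time < 0)
  st <- sequence_test(subset_neurons(tn, pre),
                      rng_seed = deepcalseq:::derive_seed(77, 1))
  expect_equal(wa$p_value, st$p_value)
  expect_equal(wa$n_neurons, length(pre))
})

test_that("window analysis reports untestable windows instead of failing", {
  # all peaks post-reward -> pre-reward windows have no eligible neurons
  tn <- make_tuned_tensor(n_neurons = 10, n_trials = 6,
                          preferred = runif(10, 2, 8), seed = 10)
  wa <- window_ridge_analysis(tn, window_len = 5, rng_seed = 1)
  expect_equal(nrow(wa), 2L)
  expect_true(all(!wa$testable))
  expect_true(all(is.na(wa$p_value)))
  # sliding mode produces the expected window grid
  tn2 <- make_tuned_tensor(n_neurons = 25, n_trials = 8,
                           preferred = runif(25, -9.5, -0.5), seed = 11)
  wa2 <- window_ridge_analysis(tn2, mode = "sliding", stride = 1,
                               rng_seed = 2)
  expect_equal(wa2$window_start, seq(-10, -5))
})
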