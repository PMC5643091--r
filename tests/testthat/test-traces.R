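test_that("block averaging takes non-overlapping means and drops the remainder", {
  tr <- fluorescence_traces(matrix(1:6, 1), frame_rate = 30)
  ba <- block_average(tr, 3)
  expect_equal(as.numeric(ba$values), c(2, 5))
  expect_equal(ba$frame_rate, 10)
  const <- fluorescence_traces(matrix(4, 2, 10), frame_rate = 30)
  bc <- block_average(const, 3)
  expect_equal(dim(bc$values), c(2L, 3L))
  expect_true(all(bc$values == 4))
  expect_error(block_average(tr, 7), class = "deepcalseq_invalid")
})

test_that("block averaging matches a loop-based oracle on random traces", {
  set.seed(5)
  v <- matrix(rnorm(3 * 100), 3, 100)
  tr <- fluorescence_traces(v, frame_rate = 30)
  for (k in c(2, 3, 7)) {
    got <- block_average(tr, k)$values
    m <- ncol(v) %/% k
    oracle <- sapply(seq_len(m), function(b)
      rowMeans(v[, ((b - 1) * k + 1):(b * k), drop = FALSE]))
    expect_equal(unname(got), unname(oracle))
  }
})

test_that("percentile detrending handles constant and constructed baselines", {
  tr <- fluorescence_traces(matrix(100, 1, 50), frame_rate = 10)
  expect_true(all(percentile_detrend(tr, half_window = 2)$values == 0))
  # trace where the 8th percentile of every window is 100
  x <- rep(100, 60); x[30] <- 150
  d <- percentile_detrend(fluorescence_traces(matrix(x, 1), frame_rate = 10),
                          half_window = 2)
  expect_equal(unname(d$values[1, 30]), 0.5)
  expect_equal(unname(d$values[1, 10]), 0)
  # non-positive baseline errors with neuron and frame
  bad <- fluorescence_traces(matrix(c(rep(-1, 30), rep(5, 30)), 1),
                             frame_rate = 10)
  expect_error(percentile_detrend(bad, half_window = 2),
               class = "deepcalseq_degenerate_baseline")
})

test_that("percentile detrending equals a per-frame brute-force percentile", {
  set.seed(21)
  for (i in 1:5) {
    n <- 80
    x <- 100 + cumsum(rnorm(n, 0, 1)) + 30 * (runif(n) < 0.05)
    hw_s <- sample(2:5, 1)
    tr <- fluorescence_traces(matrix(x, 1), frame_rate = 10)
    d <- percentile_detrend(tr, half_window = hw_s, percentile = 8)
    hw <- hw_s * 10
    f0 <- vapply(seq_len(n), function(t)
      quantile(x[max(1, t - hw):min(n, t + hw)], 0.08, type = 7,
               names = FALSE), numeric(1))
    expect_identical(as.numeric(d$values[1, ]), (x - f0) / f0)
  }
})

test_that("dF/F is invariant under positive rescaling of the raw trace", {
  set.seed(9)
  x <- 50 + abs(rnorm(100, 0, 5))
  d1 <- percentile_detrend(fluorescence_traces(matrix(x, 1), 10),
                           half_window = 3)
  d2 <- percentile_detrend(fluorescence_traces(matrix(7 * x, 1), 10),
                           half_window = 3)
  expect_equal(d1$values, d2$values, tolerance = 1e-12)
})

test_that("trial alignment gates on licks and respects recording bounds", {
  f <- 10
  nfr <- 2200 # 220 s at 10 Hz
  dff <- deepcalseq:::new_dff_traces(matrix(0, 2, nfr), f, 0)
  dels <- 20 * (1:10)
  licks <- dels + 0.5
  tensor <- align_trials(dff, event_list(dels, sort(licks)))
  expect_equal(dim(tensor$values), c(2L, 10L, 200L))
  expect_equal(tensor$time_axis[1], -9.95)
  expect_equal(tensor$time_axis[200], 9.95)
  expect_equal(max(abs(tensor$time_axis + rev(tensor$time_axis))), 0)

  # first lick at +2.5 s -> that delivery is excluded
  licks2 <- licks; licks2[4] <- dels[4] + 2.5
  t2 <- align_trials(dff, event_list(dels, sort(licks2)))
  expect_equal(dim(t2$values)[2], 9L)
  expect_equal(t2$trial_log$status[4], "no_lick")

  # delivery 5 s before the end of the recording is dropped with a warning
  dels3 <- c(dels, 215)
  expect_warning(
    t3 <- align_trials(dff, event_list(dels3, c(sort(licks), 215.3))),
    "dropped")
  expect_equal(t3$trial_log$status[11], "out_of_range")

  expect_error(align_trials(dff, event_list(dels, numeric())),
               class = "deepcalseq_empty_tensor")
})

test_that("aligned windows carry the correct dF/F segments", {
  f <- 10; nfr <- 600
  vals <- matrix(seq_len(nfr), 1, nfr) # trace = frame index
  dff <- deepcalseq:::new_dff_traces(vals, f, 0)
  tensor <- align_trials(dff, event_list(30, 30.4))
  # first frame centre >= 20 s is frame 201 (centre 20.05)
  expect_equal(as.numeric(tensor$values[1, 1, ]), 201:400)
})

test_that("trial averaging, normalization and peak times behave as stated", {
  tn <- make_tuned_tensor(n_neurons = 5, n_trials = 1, seed = 2)
  avg <- trial_average(tn)
  expect_equal(unname(avg$traces), unname(tn$values[, 1, ]))

  # a symmetric bump at -3 s in every trial peaks at -3 s
  axis <- tn$time_axis
  bump <- bump_on_axis(axis, -3)
  vals <- aperm(array(rep(bump, 3 * 4), dim = c(length(axis), 3, 4)),
                c(2, 3, 1))
  a2 <- trial_average(make_tensor(vals))
  expect_true(all(abs(a2$peak_time - (-3)) <= 0.05 + 1e-9))

  set.seed(4)
  vr <- array(rnorm(6 * 5 * 40), dim = c(6, 5, 40))
  t3 <- make_tensor(vr)
  a3 <- trial_average(t3, normalize = TRUE)
  oracle <- t(sapply(1:6, function(i) colMeans(vr[i, , ])))
  a3u <- trial_average(t3)
  expect_equal(unname(a3u$traces), unname(oracle))
  expect_equal(a3u$peak_index,
               apply(oracle, 1, which.max))
  expect_true(all(abs(apply(a3$traces, 1, min)) < 1e-12))
  expect_true(all(abs(apply(a3$traces, 1, max) - 1) < 1e-12))

  # constant neuron flagged under normalization
  vc <- array(1, dim = c(1, 3, 40))
  ac <- trial_average(make_tensor(vc), normalize = TRUE)
  expect_true(ac$constant[1])
  expect_true(is.na(ac$peak_time[1]))
})

test_that("activity drift check separates stationary from scaled sessions", {
  set.seed(13)
  vals <- matrix(abs(rnorm(20 * 7000, 1, 0.2)), 20, 7000)
  dff <- deepcalseq:::new_dff_traces(vals, 10, 0)
  dc <- activity_drift_check(dff, period = 300)
  expect_gt(dc$p_value, 0.05)
  expect_lt(abs(dc$mean_diff), 0.02)

  # identical first and last windows -> difference exactly 0
  vals2 <- vals
  vals2[, 4001:7000] <- vals2[, 1:3000]
  dc2 <- activity_drift_check(deepcalseq:::new_dff_traces(vals2, 10, 0), 300)
  expect_equal(dc2$mean_diff, 0)
  expect_equal(dc2$p_value, 1)

  # doubled late amplitudes are detected
  vals3 <- vals
  vals3[, 4001:7000] <- vals3[, 4001:7000] * 2
  dc3 <- activity_drift_check(deepcalseq:::new_dff_traces(vals3, 10, 0), 300)
  expect_lt(dc3$p_value, 0.001)

  expect_error(activity_drift_check(
    deepcalseq:::new_dff_traces(vals[, 1:100, drop = FALSE], 10, 0), 300),
    class = "deepcalseq_invalid")
})
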