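# Fixture builders used across test files.  Everything is generated in
# code under fixed seeds; nothing is read from disk.

# A trial tensor built directly from an array (bypassing align_trials),
# with the standard [-10, 10) s axis.
make_tensor <- function(values, frame_rate = 10) {
  d <- dim(values)
  dt <- 1 / frame_rate
  if (is.null(dimnames(values)[[1]])) {
    dimnames(values) <- list(sprintf("n%03d", seq_len(d[1])), NULL, NULL)
  }
  structure(
    list(values = values,
         time_axis = -10 + (seq_len(d[3]) - 0.5) * dt,
         frame_rate = frame_rate,
         included_trials = seq_len(d[2]),
         trial_log = tibble::tibble(delivery_time = 20 * seq_len(d[2]),
                                    status = "included")),
    class = "trial_tensor"
  )
}

# Gaussian activity bump evaluated on the 10 Hz trial axis.
bump_on_axis <- function(axis, center, width = 0.8, amplitude = 1) {
  amplitude * exp(-(axis - center)^2 / (2 * width^2))
}

# Tensor of temporally tuned neurons: one bump per trial at
# preferred + jitter, plus optional Gaussian noise.
make_tuned_tensor <- function(n_neurons = 50, n_trials = 20,
                              preferred = NULL, jitter_sd = 0,
                              noise_sd = 0, frame_rate = 10, seed = 1) {
  f <- as.integer(20 * frame_rate)
  axis <- -10 + (seq_len(f) - 0.5) / frame_rate
  withr::with_seed(seed, {
    if (is.null(preferred)) preferred <- runif(n_neurons, -9, 9)
    vals <- array(0, dim = c(n_neurons, n_trials, f))
    for (i in seq_len(n_neurons)) {
      for (j in seq_len(n_trials)) {
        c0 <- preferred[i] + if (jitter_sd > 0) rnorm(1, 0, jitter_sd) else 0
        vals[i, j, ] <- bump_on_axis(axis, c0)
      }
    }
    if (noise_sd > 0) vals <- vals + array(rnorm(length(vals), 0, noise_sd),
                                           dim = dim(vals))
    tn <- make_tensor(vals, frame_rate)
    attr(tn, "preferred") <- preferred
    tn
  })
}

# Tensor of untuned neurons: an independent uniformly placed bump per trial.
make_random_peak_tensor <- function(n_neurons = 60, n_trials = 20,
                                    frame_rate = 10, seed = 1) {
  f <- as.integer(20 * frame_rate)
  axis <- -10 + (seq_len(f) - 0.5) / frame_rate
  withr::with_seed(seed, {
    vals <- array(0, dim = c(n_neurons, n_trials, f))
    for (i in seq_len(n_neurons)) {
      for (j in seq_len(n_trials)) {
        vals[i, j, ] <- bump_on_axis(axis, runif(1, -9.5, 9.5))
      }
    }
    make_tensor(vals, frame_rate)
  })
}

# Match circle detections to planted truth; returns recall and false
# positives (detections not within tol pixels of any planted centre).
match_detections <- function(det, truth, tol = 2) {
  if (nrow(det) == 0L) return(list(recall = 0, fp = 0))
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any((det$y - truth$y[i])^2 + (det$x - truth$x[i])^2 <= tol^2)
  }, logical(1))
  used <- vapply(seq_len(nrow(det)), function(k) {
    any((det$y[k] - truth$y)^2 + (det$x[k] - truth$x)^2 <= tol^2)
  }, logical(1))
  list(recall = mean(hit), fp = sum(!used))
}
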