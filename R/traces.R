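#' Raw fluorescence traces
#'
#' Neurons-by-frames matrix of extracted somatic fluorescence, with the
#' acquisition frame rate and the session-clock time of the first frame.
#' Frame `i` is timestamped at its bin centre,
#' `start_time + (i - 0.5) / frame_rate`.
#'
#' @param values Numeric matrix, rows = neurons, columns = frames; all
#'   values finite.
#' @param frame_rate Acquisition rate, Hz.
#' @param start_time Session time of the start of frame 1, s.
#' @return An object of class `fluorescence_traces`.
#' @export
fluorescence_traces <- function(values, frame_rate = 30, start_time = 0) {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values))) {
    stop_invalid("`values` must be a finite numeric matrix (neurons x frames)")
  }
  check_number(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  check_number(start_time, "start_time")
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("n%03d", seq_len(nrow(values)))
  }
  structure(list(values = values, frame_rate = frame_rate,
                 start_time = start_time),
            class = "fluorescence_traces")
}

new_dff_traces <- function(values, frame_rate, start_time) {
  structure(list(values = values, frame_rate = frame_rate,
                 start_time = start_time),
            class = "dff_traces")
}

#' @export
print.fluorescence_traces <- function(x, ...) {
  cat(sprintf("<fluorescence_traces> %d neurons x %d frames at %g Hz (start %g s)\n",
              nrow(x$values), ncol(x$values), x$frame_rate, x$start_time))
  invisible(x)
}

#' @export
print.dff_traces <- function(x, ...) {
  cat(sprintf("<dff_traces> %d neurons x %d frames at %g Hz (start %g s)\n",
              nrow(x$values), ncol(x$values), x$frame_rate, x$start_time))
  invisible(x)
}

#' Frame-centre timestamps of a trace object
#' @param x A `fluorescence_traces` or `dff_traces` object.
#' @return Numeric vector of session times, s.
#' @export
frame_times <- function(x) {
  x$start_time + (seq_len(ncol(x$values)) - 0.5) / x$frame_rate
}

#' Behavioural event list
#'
#' Water-delivery and lick timestamps on the session clock.
#'
#' @param delivery_times Strictly increasing delivery times, s.
#' @param lick_times Non-decreasing lick times, s (may be empty).
#' @return An object of class `event_list`.
#' @export
event_list <- function(delivery_times, lick_times = numeric()) {
  delivery_times <- as.numeric(delivery_times)
  lick_times <- as.numeric(lick_times)
  if (length(delivery_times) == 0L || !all(is.finite(delivery_times))) {
    stop_invalid("`delivery_times` must be a non-empty finite vector")
  }
  if (is.unsorted(delivery_times, strictly = TRUE)) {
    stop_invalid("`delivery_times` must be strictly increasing")
  }
  if (length(lick_times) && (any(!is.finite(lick_times)) ||
                             is.unsorted(lick_times))) {
    stop_invalid("`lick_times` must be finite and non-decreasing")
  }
  structure(list(delivery_times = delivery_times, lick_times = lick_times),
            class = "event_list")
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("<event_list> %d deliveries, %d licks\n",
              length(x$delivery_times), length(x$lick_times)))
  invisible(x)
}

#' Average non-overlapping blocks of consecutive frames
#'
#' Replaces each block of `k` consecutive frames by its mean (the standard
#' three-frame averaging that takes 30 Hz movies to a 10 Hz working rate and
#' improves signal-to-noise).  Trailing frames that do not fill a block are
#' dropped.  The new frame rate is `frame_rate / k`; bin-centre timestamps
#' remain consistent because each new frame's centre is the mean of its
#' constituent centres.
#'
#' @param traces A [fluorescence_traces()] object.
#' @param k Block length (default 3).
#' @return A `fluorescence_traces` object at the reduced rate.
#' @export
block_average <- function(traces, k = 3) {
  stopifnot(inherits(traces, "fluorescence_traces"))
  check_number(k, "k", lower = 1)
  k <- as.integer(k)
  nf <- ncol(traces$values)
  if (k > nf) stop_invalid("`k` exceeds the number of frames")
  m <- nf %/% k
  v <- traces$values[, seq_len(m * k), drop = FALSE]
  out <- v[, seq(1, m * k, by = k), drop = FALSE] * 0
  for (a in seq_len(k)) {
    out <- out + v[, seq(a, m * k, by = k), drop = FALSE]
  }
  fluorescence_traces(out / k, frame_rate = traces$frame_rate / k,
                      start_time = traces$start_time)
}

#' Percentile-baseline dF/F detrending
#'
#' For every frame `t` the baseline `F0(t)` is a low percentile (default the
#' 8th) of the raw trace within a sliding window of `t +/- half_window`
#' seconds, truncated at the trace edges; the detrended relative
#' fluorescence change is `(F - F0) / F0`.  Tracking a running percentile
#' removes slow drift (photobleaching, z-drift) while the low percentile is
#' insensitive to the sparse positive calcium transients riding on the
#' baseline.  Percentiles use linear interpolation between order statistics
#' (the convention of [stats::quantile()] type 7).
#'
#' @param traces A [fluorescence_traces()] object with strictly positive
#'   baseline fluorescence.
#' @param half_window Half width of the baseline window, s (default 30).
#' @param percentile Baseline percentile in (0, 100) (default 8).
#' @return A `dff_traces` object of the same shape.
#' @export
percentile_detrend <- function(traces, half_window = 30, percentile = 8) {
  stopifnot(inherits(traces, "fluorescence_traces"))
  check_number(half_window, "half_window", lower = 0, strict_lower = TRUE)
  check_number(percentile, "percentile", lower = 0, upper = 100,
               strict_lower = TRUE)
  nf <- ncol(traces$values)
  if (nf < 3L) stop_invalid("trace too short to detrend")
  hw <- as.integer(round(half_window * traces$frame_rate))
  p <- percentile / 100
  vals <- traces$values
  out <- vals
  for (i in seq_len(nrow(vals))) {
    f0 <- run_quantile_cpp(vals[i, ], hw, p)
    bad <- which(f0 <= 0)
    if (length(bad)) {
      abort(sprintf(
        "degenerate baseline: F0 <= 0 for neuron %s at frame %d",
        rownames(vals)[i] %||% i, bad[1]),
        class = c("deepcalseq_degenerate_baseline", "deepcalseq_error"))
    }
    out[i, ] <- (vals[i, ] - f0) / f0
  }
  new_dff_traces(out, traces$frame_rate, traces$start_time)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Lick-gated trial alignment of dF/F traces
#'
#' Extracts, for every water delivery at which the animal licked within the
#' response window, the dF/F segment from `window[1]` to `window[2]` seconds
#' around the delivery, forming a neurons x trials x frames tensor.
#' Deliveries without a lick in `(delivery, delivery + response_window]` are
#' excluded (the animal did not respond); deliveries whose window extends
#' past the recorded session are dropped with a warning.
#'
#' The relative time axis holds bin centres and is symmetric about 0
#' (e.g. -9.95, ..., +9.95 s at 10 Hz); time 0 maps to the first frame whose
#' centre is at or after the delivery.
#'
#' @param dff A `dff_traces` object (see [percentile_detrend()]).
#' @param events An [event_list()].
#' @param window Two-element window around delivery, s (default `c(-10, 10)`).
#' @param response_window Lick-response window after delivery, s (default 2).
#' @return An object of class `trial_tensor` with elements `values`
#'   (neurons x trials x frames), `time_axis`, `frame_rate`,
#'   `included_trials` (delivery indices), and `trial_log` (a tibble with
#'   one row per delivery recording inclusion and reason).
#' @export
align_trials <- function(dff, events, window = c(-10, 10),
                         response_window = 2) {
  stopifnot(inherits(dff, "dff_traces"), inherits(events, "event_list"))
  if (length(window) != 2L || window[1] >= window[2]) {
    stop_invalid("`window` must be c(start, end) with start < end")
  }
  check_number(response_window, "response_window", lower = 0,
               strict_lower = TRUE)
  rate <- dff$frame_rate
  dt <- 1 / rate
  nf <- as.integer(round((window[2] - window[1]) * rate))
  axis <- window[1] + (seq_len(nf) - 0.5) * dt
  nfr_total <- ncol(dff$values)
  n <- nrow(dff$values)

  dels <- events$delivery_times
  licks <- events$lick_times
  responsive <- vapply(dels, function(d) {
    any(licks > d & licks <= d + response_window)
  }, logical(1))

  # first frame whose centre is >= delivery + window[1]
  first_idx <- as.integer(ceiling(
    (dels + window[1] - dff$start_time) * rate + 0.5 - 1e-9))
  in_range <- first_idx >= 1L & (first_idx + nf - 1L) <= nfr_total

  status <- dplyr::case_when(
    !responsive ~ "no_lick",
    !in_range ~ "out_of_range",
    TRUE ~ "included"
  )
  if (any(status == "out_of_range" & responsive)) {
    warn(sprintf("%d responsive deliveries dropped: window exceeds recording",
                 sum(status == "out_of_range" & responsive)))
  }
  keep <- which(status == "included")
  if (length(keep) == 0L) {
    abort("no responsive deliveries with full trace coverage",
          class = c("deepcalseq_empty_tensor", "deepcalseq_error"))
  }
  vals <- array(NA_real_, dim = c(n, length(keep), nf),
                dimnames = list(rownames(dff$values), NULL, NULL))
  for (j in seq_along(keep)) {
    i0 <- first_idx[keep[j]]
    vals[, j, ] <- dff$values[, i0:(i0 + nf - 1L)]
  }
  structure(
    list(values = vals, time_axis = axis, frame_rate = rate,
         included_trials = keep,
         trial_log = tibble::tibble(delivery_time = dels, status = status)),
    class = "trial_tensor"
  )
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<trial_tensor> %d neurons x %d trials x %d frames, [%g, %g] s at %g Hz\n",
              d[1], d[2], d[3], x$time_axis[1] - 0.5 / x$frame_rate,
              x$time_axis[d[3]] + 0.5 / x$frame_rate, x$frame_rate))
  invisible(x)
}

#' Restrict a trial tensor to a subset of neurons
#' @param tensor A `trial_tensor`.
#' @param idx Neuron indices (or names) to keep.
#' @return A `trial_tensor` with the selected neurons.
#' @export
subset_neurons <- function(tensor, idx) {
  stopifnot(inherits(tensor, "trial_tensor"))
  out <- tensor
  out$values <- tensor$values[idx, , , drop = FALSE]
  out
}

#' Trial-averaged activity and peak times
#'
#' Averages the tensor over trials for each neuron, optionally min-max
#' normalises each neuron's averaged trace to \[0, 1\] (the convention used
#' for peak-ordered raster displays), and extracts the time of peak
#' activity.  Ties are broken toward the earliest frame.  Neurons whose
#' averaged trace is constant are flagged and get `NA` peak times.
#'
#' @param tensor A `trial_tensor` from [align_trials()].
#' @param normalize Min-max scale each neuron's average to \[0, 1\]?
#' @return An object of class `trial_avg`: `traces` (neurons x frames),
#'   `time_axis`, `peak_time`, `peak_index`, `order` (display order by peak
#'   time), `constant` (logical), `normalized`.
#' @export
trial_average <- function(tensor, normalize = FALSE) {
  stopifnot(inherits(tensor, "trial_tensor"))
  d <- dim(tensor$values)
  if (d[2] < 1L) stop_invalid("tensor has no trials")
  avg <- colMeans(aperm(tensor$values, c(2, 1, 3)))  # neurons x frames
  dim(avg) <- c(d[1], d[3])
  rownames(avg) <- dimnames(tensor$values)[[1]]
  rng <- matrixStats_range(avg)
  constant <- rng[, 2] == rng[, 1]
  peak_idx <- max.col(avg, ties.method = "first")
  peak_idx[constant] <- NA_integer_
  peak_time <- tensor$time_axis[peak_idx]
  if (normalize) {
    span <- rng[, 2] - rng[, 1]
    span[constant] <- 1
    avg <- (avg - rng[, 1]) / span
  }
  structure(
    list(traces = avg, time_axis = tensor$time_axis,
         peak_time = peak_time, peak_index = peak_idx,
         order = order(peak_time, na.last = TRUE),
         constant = constant, normalized = normalize),
    class = "trial_avg"
  )
}

# rowwise range without matrixStats
matrixStats_range <- function(m) {
  cbind(apply(m, 1, min), apply(m, 1, max))
}

#' @export
print.trial_avg <- function(x, ...) {
  cat(sprintf("<trial_avg> %d neurons x %d frames%s\n",
              nrow(x$traces), ncol(x$traces),
              if (x$normalized) " (min-max normalized)" else ""))
  invisible(x)
}

#' First-versus-last period activity drift check
#'
#' Compares each neuron's mean dF/F in the first and last `period` seconds
#' of a session with a paired two-tailed t-test across neurons; used to
#' verify that prolonged high-power imaging did not alter excitability over
#' the session.
#'
#' @param dff A `dff_traces` object.
#' @param period Window length, s (default 300 = 5 min).
#' @return An object of class `drift_check`: per-neuron tibble
#'   (`first_mean`, `last_mean`, `diff`), overall `mean_diff`, `statistic`
#'   and `p_value`.
#' @export
activity_drift_check <- function(dff, period = 300) {
  stopifnot(inherits(dff, "dff_traces"))
  check_number(period, "period", lower = 0, strict_lower = TRUE)
  nf <- ncol(dff$values)
  fp <- as.integer(round(period * dff$frame_rate))
  if (nf < 2L * fp) stop_invalid("session shorter than 2 * period")
  first_mean <- rowMeans(dff$values[, seq_len(fp), drop = FALSE])
  last_mean <- rowMeans(dff$values[, seq.int(nf - fp + 1L, nf), drop = FALSE])
  diffs <- last_mean - first_mean
  tt <- if (sd(diffs) == 0) {
    list(statistic = c(t = 0), p.value = 1)
  } else {
    t.test(last_mean, first_mean, paired = TRUE)
  }
  structure(
    list(per_neuron = tibble::tibble(
           neuron = rownames(dff$values) %||% seq_along(first_mean),
           first_mean = first_mean, last_mean = last_mean, diff = diffs),
         mean_diff = mean(diffs),
         statistic = unname(tt$statistic),
         p_value = tt$p.value,
         period = period),
    class = "drift_check"
  )
}

#' @export
print.drift_check <- function(x, ...) {
  cat(sprintf(
    "<drift_check> %d neurons, %g s windows: mean diff %.4g, paired t p = %.3g\n",
    nrow(x$per_neuron), x$period, x$mean_diff, x$p_value))
  invisible(x)
}
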