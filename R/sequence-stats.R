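#' Ridge-to-background ratio of trial-averaged traces
#'
#' For each neuron, the "ridge" dF/F is the mean over a `ridge_frames`-long
#' window containing the time of peak activity of the trial-averaged trace
#' (6 frames before through 5 after the peak for the default 12 frames at
#' 10 Hz; peaks near the edge use the nearest fully in-range window), the
#' "background" dF/F is the mean over all remaining frames, and the ratio
#' quantifies how concentrated the neuron's activity is at its preferred
#' time.  A flat trace has ratio 1.  Neurons with a constant average or with
#' non-positive background get `NA` ratios and are flagged `degenerate`.
#'
#' @param avg A `trial_avg` object from [trial_average()] (unnormalized
#'   traces are used for the statistic).
#' @param ridge_frames Ridge window length in frames (default 12, i.e.
#'   1.2 s at the 10 Hz working rate).
#' @return A tibble of class `ridge_stats` with columns `neuron`,
#'   `peak_time`, `ridge_dff`, `background_dff`, `ratio`, `degenerate`.
#' @export
ridge_to_background <- function(avg, ridge_frames = 12) {
  stopifnot(inherits(avg, "trial_avg"))
  if (isTRUE(avg$normalized)) {
    warn("ridge statistics are normally computed on unnormalized averages")
  }
  check_number(ridge_frames, "ridge_frames", lower = 1)
  ridge_frames <- as.integer(ridge_frames)
  f <- ncol(avg$traces)
  if (f <= ridge_frames) stop_invalid("trace shorter than the ridge window")
  before <- ridge_frames %/% 2L

  n <- nrow(avg$traces)
  ridge <- background <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (avg$constant[i]) next
    p <- avg$peak_index[i]
    lo <- p - before
    lo <- min(max(lo, 1L), f - ridge_frames + 1L)
    win <- lo:(lo + ridge_frames - 1L)
    ridge[i] <- mean(avg$traces[i, win])
    background[i] <- mean(avg$traces[i, -win])
  }
  ratio <- ridge / background
  degenerate <- avg$constant | (!is.na(background) & background <= 0)
  ratio[degenerate] <- NA_real_
  out <- tibble::tibble(
    neuron = rownames(avg$traces) %||% as.character(seq_len(n)),
    peak_time = avg$peak_time,
    ridge_dff = ridge,
    background_dff = background,
    ratio = ratio,
    degenerate = degenerate
  )
  attr(out, "ridge_frames") <- ridge_frames
  class(out) <- c("ridge_stats", class(out))
  out
}

#' Circular-shift shuffle of a trial tensor
#'
#' Constructs the timing-destroying null: each neuron's trace in each trial
#' is circularly rotated by an independent uniform whole-frame offset, the
#' rotated trials are averaged, and ridge statistics are recomputed on the
#' shuffled averages (the shuffled peak is found anew, not inherited).
#' Rotation is a permutation, so each trial's multiset of dF/F values is
#' preserved exactly; only consistent timing across trials is destroyed.
#'
#' @param tensor A `trial_tensor`.
#' @param rng_seed Integer seed for the shift draws.
#' @param ridge_frames Passed to [ridge_to_background()].
#' @param shifts Optional neurons x trials integer matrix of shifts in
#'   `[0, frames)`, overriding the random draws (useful for testing; all
#'   zeros reproduces the original averages).
#' @return An object of class `shuffle_result`: `avg` (a `trial_avg` of the
#'   shuffled data), `stats` (its `ridge_stats`), `shifts`, `rng_seed`.
#' @export
circular_shuffle <- function(tensor, rng_seed = 1, ridge_frames = 12,
                             shifts = NULL) {
  stopifnot(inherits(tensor, "trial_tensor"))
  d <- dim(tensor$values)
  if (d[2] < 1L) stop_invalid("tensor has no trials")
  n <- d[1]; ntr <- d[2]; f <- d[3]
  if (is.null(shifts)) {
    shifts <- withr::with_seed(as.integer(rng_seed),
      matrix(sample.int(f, n * ntr, replace = TRUE) - 1L, n, ntr))
  }
  stopifnot(all(dim(shifts) == c(n, ntr)), all(shifts >= 0), all(shifts < f))

  acc <- matrix(0, n, f)
  rows <- rep(seq_len(n), f)
  base <- matrix(rep(0:(f - 1L), each = n), n, f)
  for (j in seq_len(ntr)) {
    cols <- ((base + shifts[, j]) %% f) + 1L
    m <- tensor$values[, j, ]
    dim(m) <- c(n, f)
    acc <- acc + matrix(m[cbind(rows, as.vector(cols))], n, f)
  }
  avg_mat <- acc / ntr
  rownames(avg_mat) <- dimnames(tensor$values)[[1]]
  avg <- as_trial_avg(avg_mat, tensor$time_axis)
  structure(
    list(avg = avg, stats = ridge_to_background(avg, ridge_frames),
         shifts = shifts, rng_seed = rng_seed),
    class = "shuffle_result"
  )
}

# wrap a plain averaged matrix as a trial_avg (shared by shuffle paths)
as_trial_avg <- function(avg_mat, time_axis) {
  rng <- matrixStats_range(avg_mat)
  constant <- rng[, 2] == rng[, 1]
  peak_idx <- max.col(avg_mat, ties.method = "first")
  peak_idx[constant] <- NA_integer_
  structure(
    list(traces = avg_mat, time_axis = time_axis,
         peak_time = time_axis[peak_idx], peak_index = peak_idx,
         order = order(time_axis[peak_idx], na.last = TRUE),
         constant = constant, normalized = FALSE),
    class = "trial_avg"
  )
}

#' Ridge-to-background sequence test
#'
#' Tests whether the peak-ordered sequential structure of trial-averaged
#' activity exceeds what random trial timing would produce: ridge-to-
#' background ratios of the original averages are compared with those of a
#' circular-shift shuffle of the same tensor by a two-tailed Wilcoxon
#' rank-sum test across neurons.
#'
#' @inheritParams circular_shuffle
#' @return An object of class `seq_test`: `original` and `shuffled`
#'   `ridge_stats` tibbles, `p_value`, `statistic`, `n_neurons` (with
#'   defined ratios in each distribution), `rng_seed`.
#' @export
sequence_test <- function(tensor, rng_seed = 1, ridge_frames = 12,
                          shifts = NULL) {
  stopifnot(inherits(tensor, "trial_tensor"))
  orig_avg <- trial_average(tensor)
  orig <- ridge_to_background(orig_avg, ridge_frames)
  sh <- circular_shuffle(tensor, rng_seed = rng_seed,
                         ridge_frames = ridge_frames, shifts = shifts)
  ro <- orig$ratio[!orig$degenerate]
  rs <- sh$stats$ratio[!sh$stats$degenerate]
  if (length(ro) < 2L || length(rs) < 2L) {
    stop_insufficient("fewer than 2 neurons with defined ratios")
  }
  wt <- suppressWarnings(wilcox.test(ro, rs, alternative = "two.sided"))
  structure(
    list(original = orig, shuffled = sh$stats,
         p_value = wt$p.value, statistic = unname(wt$statistic),
         n_original = length(ro), n_shuffled = length(rs),
         ridge_frames = ridge_frames, rng_seed = rng_seed),
    class = "seq_test"
  )
}

#' @export
print.seq_test <- function(x, ...) {
  cat(sprintf(
    "<seq_test> %d neurons: mean ratio %.3f (original) vs %.3f (shuffled), rank-sum p = %.3g\n",
    x$n_original, mean(x$original$ratio, na.rm = TRUE),
    mean(x$shuffled$ratio, na.rm = TRUE), x$p_value))
  invisible(x)
}

#' Histogram of peak-activity times
#'
#' Counts of per-neuron peak times in fixed-width bins over the trial
#' window, left-closed right-open (default 0.5 s bins over \[-10, 10)).
#' Neurons without a defined peak are excluded; counts sum to the number of
#' neurons with defined peaks.
#'
#' @param stats A `ridge_stats` tibble (or any tibble with `peak_time`).
#' @param bin_width Bin width, s.
#' @param range Two-element time range, s.
#' @return A tibble of class `peak_histogram` with `bin_start`, `bin_end`,
#'   `count`.
#' @export
peak_time_histogram <- function(stats, bin_width = 0.5, range = c(-10, 10)) {
  pt <- stats$peak_time
  pt <- pt[!is.na(pt)]
  if (length(pt) == 0L) stop_insufficient("no defined peak times")
  breaks <- seq(range[1], range[2], by = bin_width)
  nb <- length(breaks) - 1L
  idx <- findInterval(pt, breaks, left.open = FALSE, rightmost.closed = FALSE)
  idx <- idx[idx >= 1L & idx <= nb]
  out <- tibble::tibble(
    bin_start = breaks[-length(breaks)],
    bin_end = breaks[-1],
    count = tabulate(idx, nbins = nb)
  )
  class(out) <- c("peak_histogram", class(out))
  out
}

#' Fraction of neurons with peak activity in an interval
#'
#' Fraction of neurons (among those with a defined peak) whose peak time
#' falls in the half-open interval `[interval[1], interval[2])`; fractions
#' over a partition of the trial window sum to 1.
#'
#' @param stats A `ridge_stats` tibble.
#' @param interval Two-element interval, s.
#' @return Fraction in \[0, 1\].
#' @export
peak_fraction_in_interval <- function(stats, interval) {
  pt <- stats$peak_time
  pt <- pt[!is.na(pt)]
  if (length(pt) == 0L) stop_insufficient("no defined peak times")
  mean(pt >= interval[1] & pt < interval[2])
}

#' Per-window pre-reward ridge analysis
#'
#' Slides (or stacks) windows of length `window_len` seconds across the
#' pre-reward period \[-10, 0), restricts to neurons whose original
#' trial-averaged peak falls in each window, and runs [sequence_test()] on
#' that subset.  Windows with fewer than 2 eligible neurons are reported as
#' not testable.
#'
#' @inheritParams circular_shuffle
#' @param window_len Window length, s (default 5).
#' @param mode `"disjoint"` stacks non-overlapping windows
#'   (\[-10, -5), \[-5, 0) at the default length); `"sliding"` advances by
#'   `stride` seconds.
#' @param stride Stride for sliding mode, s.
#' @return A tibble with one row per window: `window_start`, `window_end`,
#'   `n_neurons`, `testable`, `p_value`, `mean_ratio_original`,
#'   `mean_ratio_shuffled`.
#' @export
window_ridge_analysis <- function(tensor, window_len = 5,
                                  mode = c("disjoint", "sliding"),
                                  stride = 1, rng_seed = 1,
                                  ridge_frames = 12) {
  stopifnot(inherits(tensor, "trial_tensor"))
  mode <- match.arg(mode)
  if (tensor$time_axis[1] > -10 + 1 / tensor$frame_rate) {
    stop_invalid("tensor does not cover the pre-reward period [-10, 0)")
  }
  starts <- if (mode == "disjoint") {
    seq(-10, -window_len, by = window_len)
  } else {
    seq(-10, -window_len, by = stride)
  }
  avg <- trial_average(tensor)
  stats <- ridge_to_background(avg, ridge_frames)
  purrr::map_dfr(seq_along(starts), function(k) {
    a <- starts[k]; b <- a + window_len
    idx <- which(!is.na(stats$peak_time) &
                   stats$peak_time >= a & stats$peak_time < b)
    if (length(idx) < 2L) {
      return(tibble::tibble(window_start = a, window_end = b,
                            n_neurons = length(idx), testable = FALSE,
                            p_value = NA_real_,
                            mean_ratio_original = NA_real_,
                            mean_ratio_shuffled = NA_real_))
    }
    st <- sequence_test(subset_neurons(tensor, idx),
                        rng_seed = derive_seed(rng_seed, k),
                        ridge_frames = ridge_frames)
    tibble::tibble(window_start = a, window_end = b,
                   n_neurons = length(idx), testable = TRUE,
                   p_value = st$p_value,
                   mean_ratio_original = mean(st$original$ratio, na.rm = TRUE),
                   mean_ratio_shuffled = mean(st$shuffled$ratio, na.rm = TRUE))
  })
}
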