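# Trial-by-trial stability of peak timing.

# Flatten a tensor to a (neurons*frames) x trials matrix so half-averages
# are single mat-vec products; row block order matches dim c(n, f).
flatten_tensor <- function(tensor) {
  d <- dim(tensor$values)
  m <- aperm(tensor$values, c(1, 3, 2))
  dim(m) <- c(d[1] * d[3], d[2])
  m
}

# peak times of all neurons for one half-average (ties -> earliest frame)
half_peak_times <- function(PM, w, n, f, time_axis, neurons = NULL) {
  avg <- PM %*% w
  dim(avg) <- c(n, f)
  if (!is.null(neurons)) avg <- avg[neurons, , drop = FALSE]
  idx <- max.col(avg, ties.method = "first")
  constant <- rowSums(avg != avg[, 1]) == 0
  idx[constant] <- NA_integer_
  time_axis[idx]
}

split_weights <- function(ntr) {
  perm <- sample.int(ntr)
  k <- ceiling(ntr / 2)
  w1 <- numeric(ntr); w2 <- numeric(ntr)
  w1[perm[seq_len(k)]] <- 1 / k
  w2[perm[seq.int(k + 1, ntr)]] <- 1 / (ntr - k)
  list(w1 = w1, w2 = w2)
}

safe_cor <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
  cor(a[ok], b[ok])
}

#' Split-half stability of peak timing
#'
#' Quantifies whether each neuron's time of peak activity is reproducible
#' across trials.  Per repetition: trials are randomly divided into two
#' halves (sizes differing by at most 1), `n_subsample` neurons are drawn
#' without replacement (removing the effect of different population sizes
#' across imaging areas), each half is trial-averaged, the peak time of
#' every subsampled neuron is taken in each half, and the Pearson
#' correlation between the two sets of peak times is recorded.  The 95%
#' confidence interval is the 2.5th-97.5th percentile of the `n_reps`
#' correlations; a lower bound above zero is the verdict that peak timing
#' is not random across trials.
#'
#' @param tensor A `trial_tensor`, typically already restricted (via
#'   [subset_neurons()]) to neurons with pre-reward peaks.
#' @param n_subsample Neurons per repetition (default 50, the fixed panel
#'   size used to compare areas).
#' @param n_reps Number of repetitions (default 1000).
#' @param rng_seed Integer seed.
#' @param use_all If fewer than `n_subsample` neurons are available, use
#'   them all instead of refusing.
#' @return An object of class `stability_dist`: `correlations` (length
#'   `n_reps`), `ci_low`, `ci_high`, `n_subsample`, `verdict_nonrandom`,
#'   `rng_seed`.
#' @export
split_half_peak_correlation <- function(tensor, n_subsample = 50,
                                        n_reps = 1000, rng_seed = 1,
                                        use_all = FALSE) {
  stopifnot(inherits(tensor, "trial_tensor"))
  d <- dim(tensor$values)
  n <- d[1]; ntr <- d[2]; f <- d[3]
  if (ntr < 2L) stop_insufficient("need at least 2 trials to split")
  if (n < n_subsample) {
    if (!use_all) {
      stop_insufficient(sprintf(
        "only %d neurons available (< n_subsample = %d); set use_all = TRUE to override",
        n, n_subsample))
    }
    n_subsample <- n
  }
  PM <- flatten_tensor(tensor)
  corrs <- withr::with_seed(as.integer(rng_seed), {
    vapply(seq_len(n_reps), function(rep) {
      w <- split_weights(ntr)
      sub <- sample.int(n, n_subsample)
      t1 <- half_peak_times(PM, w$w1, n, f, tensor$time_axis, sub)
      t2 <- half_peak_times(PM, w$w2, n, f, tensor$time_axis, sub)
      safe_cor(t1, t2)
    }, numeric(1))
  })
  ci <- quantile(corrs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(
    list(correlations = corrs, ci_low = ci[1], ci_high = ci[2],
         n_subsample = n_subsample, n_reps = n_reps,
         verdict_nonrandom = ci[1] > 0, rng_seed = rng_seed),
    class = "stability_dist"
  )
}

#' @export
print.stability_dist <- function(x, ...) {
  cat(sprintf(
    "<stability_dist> %d reps of %d neurons: mean r = %.3f, 95%% CI [%.3f, %.3f] -> %s\n",
    x$n_reps, x$n_subsample, mean(x$correlations, na.rm = TRUE),
    x$ci_low, x$ci_high,
    if (x$verdict_nonrandom) "peak timing non-random" else "not distinguishable from random"))
  invisible(x)
}

# mean split-half r of one membership subset over n_reps fresh splits
group_mean_r <- function(PM, members, n, f, ntr, time_axis, n_reps,
                         subsample = NULL) {
  rs <- vapply(seq_len(n_reps), function(rep) {
    w <- split_weights(ntr)
    g <- if (!is.null(subsample) && length(members) > subsample) {
      members[sample.int(length(members), subsample)]
    } else members
    t1 <- half_peak_times(PM, w$w1, n, f, time_axis, g)
    t2 <- half_peak_times(PM, w$w2, n, f, time_axis, g)
    safe_cor(t1, t2)
  }, numeric(1))
  mean(rs, na.rm = TRUE)
}

#' Cross-area permutation test of peak-time stability
#'
#' Tests whether the trial-by-trial stability of pre-reward peak timing
#' differs between two imaging areas.  The observed statistic is the
#' absolute difference between the two areas' mean split-half correlations
#' (each the mean of `n_obs_reps` fresh random trial splits; both areas use
#' identically seeded split streams, so identical inputs give a difference
#' of exactly zero).  The null reassigns all neurons at random to the two
#' areas (preserving group sizes) and recomputes the statistic from one
#' fresh split per area, `n_perm` times.  The tail probability is
#' Bonferroni-scaled by `n_pairs` (default 3, the number of area pairings).
#'
#' Both tensors must share the trial count, frame count and time axis.
#'
#' @param tensor_a,tensor_b `trial_tensor`s for the two areas, restricted
#'   to pre-reward-peaked neurons.
#' @param n_perm Number of permutations (default 10000).
#' @param n_pairs Bonferroni factor (default 3).
#' @param rng_seed Integer seed.
#' @param n_obs_reps Splits used for the observed per-area means.
#' @param subsample Optional per-split neuron subsample size (disabled by
#'   default; the permutation procedure uses full reassigned memberships).
#' @return An object of class `area_perm`: `observed_abs_diff`,
#'   `null_abs_diffs`, `p_raw`, `p_corrected`, `significant`, `n_pairs`,
#'   `rng_seed`.
#' @export
area_stability_permutation <- function(tensor_a, tensor_b, n_perm = 10000,
                                       n_pairs = 3, rng_seed = 1,
                                       n_obs_reps = 1000, subsample = NULL) {
  stopifnot(inherits(tensor_a, "trial_tensor"),
            inherits(tensor_b, "trial_tensor"))
  da <- dim(tensor_a$values); db <- dim(tensor_b$values)
  if (da[1] < 1L || db[1] < 1L) stop_insufficient("both areas need neurons")
  if (da[2] != db[2] || da[3] != db[3] ||
      !isTRUE(all.equal(tensor_a$time_axis, tensor_b$time_axis))) {
    stop_invalid("the two areas must share trial count, frame count and time axis")
  }
  ntr <- da[2]; f <- da[3]
  if (ntr < 2L) stop_insufficient("need at least 2 trials")
  na_ <- da[1]; nb_ <- db[1]; n <- na_ + nb_

  pooled <- array(NA_real_, dim = c(n, ntr, f))
  pooled[seq_len(na_), , ] <- tensor_a$values
  pooled[na_ + seq_len(nb_), , ] <- tensor_b$values
  pt <- tensor_a; pt$values <- pooled
  PM <- flatten_tensor(pt)
  axis <- tensor_a$time_axis

  obs_seed <- derive_seed(rng_seed, 101)
  mA <- withr::with_seed(obs_seed,
    group_mean_r(PM, seq_len(na_), n, f, ntr, axis, n_obs_reps, subsample))
  mB <- withr::with_seed(obs_seed,
    group_mean_r(PM, na_ + seq_len(nb_), n, f, ntr, axis, n_obs_reps,
                 subsample))
  observed <- abs(mA - mB)

  null_diffs <- withr::with_seed(derive_seed(rng_seed, 202), {
    vapply(seq_len(n_perm), function(rep) {
      assign <- sample.int(n)
      gA <- assign[seq_len(na_)]
      gB <- assign[na_ + seq_len(nb_)]
      rA <- {
        w <- split_weights(ntr)
        safe_cor(half_peak_times(PM, w$w1, n, f, axis, gA),
                 half_peak_times(PM, w$w2, n, f, axis, gA))
      }
      rB <- {
        w <- split_weights(ntr)
        safe_cor(half_peak_times(PM, w$w1, n, f, axis, gB),
                 half_peak_times(PM, w$w2, n, f, axis, gB))
      }
      abs(rA - rB)
    }, numeric(1))
  })
  p_raw <- mean(null_diffs >= observed, na.rm = TRUE)
  p_corrected <- min(1, p_raw * n_pairs)
  crit <- quantile(null_diffs, 1 - 0.05 / n_pairs, na.rm = TRUE,
                   names = FALSE)
  structure(
    list(observed_abs_diff = observed,
         mean_r_a = mA, mean_r_b = mB,
         null_abs_diffs = null_diffs,
         p_raw = p_raw, p_corrected = p_corrected,
         significant = observed > crit,
         n_pairs = n_pairs, n_perm = n_perm, rng_seed = rng_seed),
    class = "area_perm"
  )
}

#' @export
print.area_perm <- function(x, ...) {
  cat(sprintf(
    "<area_perm> mean r %.3f vs %.3f, |diff| = %.4f; %d perms, corrected p = %.3g%s\n",
    x$mean_r_a, x$mean_r_b, x$observed_abs_diff, x$n_perm, x$p_corrected,
    if (x$significant) " (significant)" else ""))
  invisible(x)
}
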