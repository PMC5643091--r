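# broom-style tidy()/glance() methods for the fitted-result objects.

#' @export
tidy.trial_avg <- function(x, ...) {
  tibble::tibble(
    neuron = rep(rownames(x$traces), ncol(x$traces)),
    time_s = rep(x$time_axis, each = nrow(x$traces)),
    dff = as.vector(x$traces)
  )
}

#' @export
glance.trial_avg <- function(x, ...) {
  tibble::tibble(n_neurons = nrow(x$traces), n_frames = ncol(x$traces),
                 n_constant = sum(x$constant), normalized = x$normalized)
}

#' @export
tidy.seq_test <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$original, data = "original"),
    dplyr::mutate(x$shuffled, data = "shuffled")
  )
}

#' @export
glance.seq_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    p_value = x$p_value,
    n_original = x$n_original,
    n_shuffled = x$n_shuffled,
    mean_ratio_original = mean(x$original$ratio, na.rm = TRUE),
    mean_ratio_shuffled = mean(x$shuffled$ratio, na.rm = TRUE),
    ridge_frames = x$ridge_frames,
    rng_seed = x$rng_seed
  )
}

#' @export
tidy.stability_dist <- function(x, ...) {
  tibble::tibble(rep = seq_along(x$correlations), r = x$correlations)
}

#' @export
glance.stability_dist <- function(x, ...) {
  tibble::tibble(
    mean_r = mean(x$correlations, na.rm = TRUE),
    ci_low = x$ci_low, ci_high = x$ci_high,
    n_subsample = x$n_subsample, n_reps = x$n_reps,
    verdict_nonrandom = x$verdict_nonrandom, rng_seed = x$rng_seed
  )
}

#' @export
tidy.area_perm <- function(x, ...) {
  tibble::tibble(rep = seq_along(x$null_abs_diffs),
                 null_abs_diff = x$null_abs_diffs)
}

#' @export
glance.area_perm <- function(x, ...) {
  tibble::tibble(
    observed_abs_diff = x$observed_abs_diff,
    mean_r_a = x$mean_r_a, mean_r_b = x$mean_r_b,
    p_raw = x$p_raw, p_corrected = x$p_corrected,
    significant = x$significant, n_perm = x$n_perm, n_pairs = x$n_pairs
  )
}

#' @export
tidy.drift_check <- function(x, ...) x$per_neuron

#' @export
glance.drift_check <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, statistic = x$statistic,
                 p_value = x$p_value, period = x$period)
}

#' @export
tidy.behavior_summary <- function(x, ...) x$psth

#' @export
glance.behavior_summary <- function(x, ...) {
  tibble::tibble(response_rate = x$response_rate,
                 mean_reaction_time = x$reaction$mean_rt,
                 sem_reaction_time = x$reaction$sem_rt,
                 n_responsive = x$reaction$n)
}
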