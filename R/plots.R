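# ggplot2 figure helpers for each result type.

#' @export
autoplot.depth_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("bright_signal", "circle_count"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$depth_um, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "depth below surface (µm)", y = NULL,
                  title = "Image-quality depth profile")
}

#' Peak-ordered raster of trial-averaged activity
#'
#' Heatmap of (typically normalized) trial-averaged dF/F with neurons
#' ordered by their time of peak activity, the standard display for
#' sequential activity spanning a trial.
#'
#' @param avg A `trial_avg` object (use `normalize = TRUE` in
#'   [trial_average()] for the conventional look).
#' @return A ggplot object.
#' @export
plot_raster <- function(avg) {
  stopifnot(inherits(avg, "trial_avg"))
  ord <- avg$order
  df <- tidy.trial_avg(avg)
  df$rank <- match(df$neuron, rownames(avg$traces)[ord])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$rank,
                                   fill = .data$dff)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "ΔF/F") +
    ggplot2::labs(x = "time from water delivery (s)",
                  y = "neuron (ordered by peak time)")
}

#' @export
autoplot.trial_avg <- function(object, ...) plot_raster(object)

#' @export
autoplot.peak_histogram <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = object$bin_end[1] - object$bin_start[1]) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "red") +
    ggplot2::labs(x = "time of peak activity (s)", y = "neurons")
}

#' @export
autoplot.seq_test <- function(object, ...) {
  df <- tidy.seq_test(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio, fill = .data$data)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.5, bins = 40,
                            na.rm = TRUE) +
    ggplot2::labs(x = "ridge-to-background ratio", y = "neurons",
                  subtitle = sprintf("rank-sum p = %.3g", object$p_value))
}

#' @export
autoplot.stability_dist <- function(object, ...) {
  df <- tidy.stability_dist(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 40, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, colour = "red") +
    ggplot2::labs(x = "split-half peak-time correlation (r)",
                  y = "resamples")
}

#' @export
autoplot.lick_psth <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_mid,
                                       y = .data$rate_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$rate_mean - .data$rate_sem,
      ymax = .data$rate_mean + .data$rate_sem), alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "time from water delivery (s)", y = "licks / s")
}
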