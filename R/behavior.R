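# Conditioning-behaviour metrics: lick PSTH, response rate, reaction time.

#' Peri-delivery lick rate histogram (PSTH)
#'
#' Counts licks in fixed-width bins around each water delivery, converts to
#' rates (licks/s), and summarises as mean and standard error across
#' deliveries.  Integrating the mean rate over the window times the bin
#' width recovers the mean lick count per delivery window.
#'
#' @param events An [event_list()].
#' @param window Two-element window around delivery, s.
#' @param bin Bin width, s (default 0.5).
#' @return A tibble of class `lick_psth` with `bin_start`, `bin_end`,
#'   `t_mid`, `rate_mean`, `rate_sem`.
#' @export
lick_psth <- function(events, window = c(-10, 10), bin = 0.5) {
  stopifnot(inherits(events, "event_list"))
  check_number(bin, "bin", lower = 0, strict_lower = TRUE)
  breaks <- seq(window[1], window[2], by = bin)
  nb <- length(breaks) - 1L
  nd <- length(events$delivery_times)
  counts <- vapply(events$delivery_times, function(d) {
    rel <- events$lick_times - d
    rel <- rel[rel >= window[1] & rel < window[2]]
    tabulate(findInterval(rel, breaks), nbins = nb)
  }, numeric(nb))
  counts <- matrix(counts, nrow = nb) # nb x deliveries
  rates <- counts / bin
  out <- tibble::tibble(
    bin_start = breaks[-length(breaks)],
    bin_end = breaks[-1],
    t_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
    rate_mean = rowMeans(rates),
    rate_sem = apply(rates, 1, sd) / sqrt(nd)
  )
  class(out) <- c("lick_psth", class(out))
  out
}

#' Response rate to water delivery
#'
#' Fraction of deliveries followed by at least one lick within
#' `(delivery, delivery + response_window]`.  A lick coincident with the
#' delivery (latency exactly 0) cannot be a response and is excluded.
#'
#' @inheritParams lick_psth
#' @param response_window Response window, s (default 2).
#' @return Fraction in \[0, 1\].
#' @export
response_rate <- function(events, response_window = 2) {
  stopifnot(inherits(events, "event_list"))
  check_number(response_window, "response_window", lower = 0,
               strict_lower = TRUE)
  mean(vapply(events$delivery_times, function(d) {
    any(events$lick_times > d & events$lick_times <= d + response_window)
  }, logical(1)))
}

#' Reaction times to water delivery
#'
#' Latency from each responsive delivery to its first (strictly positive)
#' lick, with the mean and s.e.m. across responsive deliveries.
#'
#' @inheritParams response_rate
#' @return An object of class `reaction_times`: tibble `per_delivery`
#'   (`delivery_time`, `reaction_time`), `mean_rt`, `sem_rt`, `n`.
#' @export
reaction_times <- function(events, response_window = 2) {
  stopifnot(inherits(events, "event_list"))
  rt <- vapply(events$delivery_times, function(d) {
    first <- events$lick_times[events$lick_times > d &
                                 events$lick_times <= d + response_window]
    if (length(first) == 0L) NA_real_ else first[1] - d
  }, numeric(1))
  keep <- !is.na(rt)
  if (!any(keep)) {
    warn("no responsive deliveries; reaction times are empty")
  }
  structure(
    list(per_delivery = tibble::tibble(
           delivery_time = events$delivery_times[keep],
           reaction_time = rt[keep]),
         mean_rt = mean_or_na(rt[keep]),
         sem_rt = if (sum(keep) > 1L) sd(rt[keep]) / sqrt(sum(keep)) else NA_real_,
         n = sum(keep)),
    class = "reaction_times"
  )
}

#' @export
print.reaction_times <- function(x, ...) {
  cat(sprintf("<reaction_times> %d responsive deliveries: %.3f +/- %.3f s (mean +/- sem)\n",
              x$n, x$mean_rt, x$sem_rt))
  invisible(x)
}

#' Full behavioural summary of a conditioning session
#'
#' @inheritParams response_rate
#' @param window,bin Passed to [lick_psth()].
#' @return An object of class `behavior_summary` with elements `psth`,
#'   `response_rate`, `reaction` (a `reaction_times` object).
#' @export
behavior_summary <- function(events, window = c(-10, 10), bin = 0.5,
                             response_window = 2) {
  structure(
    list(psth = lick_psth(events, window, bin),
         response_rate = response_rate(events, response_window),
         reaction = reaction_times(events, response_window)),
    class = "behavior_summary"
  )
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf("<behavior_summary> response rate %.1f%%, reaction time %.0f ms\n",
              100 * x$response_rate, 1000 * (x$reaction$mean_rt %||% NA)))
  invisible(x)
}
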