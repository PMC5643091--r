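# Synthetic-data generators with full ground truth.  These state the
# "world" the downstream statistics are validated against: bright spherical
# somata under depth-dependent signal attenuation for the imaging metrics,
# and temporally tuned calcium transients in periodic-reward sessions for
# the trace statistics.

#' Parameters for a synthetic soma volume
#'
#' @param shape Volume dimensions `c(nz, ny, nx)` in voxels.
#' @param pixel_size_xy Lateral pixel size, um.
#' @param z_step Axial step, um.
#' @param depth_of_first_plane Depth of plane 1, um.
#' @param n_somata Number of planted somata.
#' @param soma_radius_range Radius range in pixels (default 6-12).
#' @param soma_intensity Soma peak intensity at zero depth, a.u.
#' @param background Background intensity, a.u.
#' @param attenuation_length Depth constant `l` of the signal attenuation
#'   `exp(-depth / l)`, um.  `Inf` disables attenuation.
#' @param noise_sd Additive Gaussian noise s.d., a.u.
#' @param non_overlapping Enforce a minimum lateral separation of
#'   `2 * r_max + 2` pixels between soma centres.
#' @param rng_seed Integer seed.
#' @return A validated list of class `volume_params`.
#' @export
volume_params <- function(shape = c(25, 256, 256), pixel_size_xy = 0.994,
                          z_step = 2.5, depth_of_first_plane = 100,
                          n_somata = 20, soma_radius_range = c(6, 12),
                          soma_intensity = 100, background = 10,
                          attenuation_length = 300, noise_sd = 2,
                          non_overlapping = TRUE, rng_seed = 1) {
  stopifnot(length(shape) == 3L, all(shape >= 1))
  check_number(n_somata, "n_somata", lower = 1)
  stopifnot(length(soma_radius_range) == 2L,
            soma_radius_range[1] <= soma_radius_range[2])
  check_number(attenuation_length, "attenuation_length", lower = 0,
               strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(shape = as.integer(shape), pixel_size_xy = pixel_size_xy,
         z_step = z_step, depth_of_first_plane = depth_of_first_plane,
         n_somata = as.integer(n_somata),
         soma_radius_range = soma_radius_range,
         soma_intensity = soma_intensity, background = background,
         attenuation_length = attenuation_length, noise_sd = noise_sd,
         non_overlapping = isTRUE(non_overlapping),
         rng_seed = as.integer(rng_seed)),
    class = "volume_params"
  )
}

place_centers <- function(n, ny, nx, r_max, min_sep, rng_max_tries = 2000) {
  margin <- r_max + 2
  ys <- numeric(0); xs <- numeric(0)
  tries <- 0
  while (length(ys) < n) {
    tries <- tries + 1
    if (tries > rng_max_tries) {
      stop_invalid("could not place non-overlapping somata; reduce n_somata or radii")
    }
    y <- runif(1, margin, ny - margin)
    x <- runif(1, margin, nx - margin)
    if (length(ys) == 0L ||
        all((ys - y)^2 + (xs - x)^2 >= min_sep^2)) {
      ys <- c(ys, y); xs <- c(xs, x)
    }
  }
  cbind(y = ys, x = xs)
}

#' Simulate a 3-D volume of bright somata with depth attenuation
#'
#' Somata are rendered as filled spheres: on each plane a soma of radius
#' `r` (pixels) centred `dz` planes away contributes a disc of in-plane
#' radius `sqrt(r^2 - (dz * z_step / pixel_size)^2)`.  The soma intensity is
#' attenuated as `exp(-depth / attenuation_length)` with depth measured
#' from the cortical surface, on top of a constant background, plus
#' additive Gaussian noise.  Placement, and noise draw from independent
#' sub-streams of `rng_seed`, so the same seed gives bit-identical voxels.
#'
#' @param params A [volume_params()] list.
#' @return A list with `stack` (an [image_stack()]) and `truth` (a list
#'   with `somata` — tibble `id`, `z`, `y`, `x`, `r_px` — and
#'   `plane_signal` — tibble `depth_um`, `expected_peak`).
#' @export
simulate_volume <- function(params = volume_params()) {
  stopifnot(inherits(params, "volume_params"))
  nz <- params$shape[1]; ny <- params$shape[2]; nx <- params$shape[3]
  r_rng <- params$soma_radius_range
  centers <- withr::with_seed(derive_seed(params$rng_seed, 1), {
    cc <- place_centers(params$n_somata, ny, nx, r_rng[2],
                        if (params$non_overlapping) 2 * r_rng[2] + 2 else 0)
    cbind(cc,
          z = runif(params$n_somata, 1, nz),
          r = runif(params$n_somata, r_rng[1], r_rng[2]))
  })
  depths <- params$depth_of_first_plane + (seq_len(nz) - 1) * params$z_step
  atten <- exp(-depths / params$attenuation_length)

  vox <- array(params$background, dim = c(nz, ny, nx))
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  for (s in seq_len(params$n_somata)) {
    cy <- centers[s, "y"]; cx <- centers[s, "x"]
    cz <- centers[s, "z"]; r <- centers[s, "r"]
    half_planes <- r * params$pixel_size_xy / params$z_step
    for (z in seq_len(nz)) {
      dz <- (z - cz) * params$z_step / params$pixel_size_xy # px
      if (abs(dz) >= r) next
      rp <- sqrt(r^2 - dz^2)
      sel <- (yy - cy)^2 + (xx - cx)^2 <= rp^2
      plane <- vox[z, , ]
      plane[sel] <- params$background + params$soma_intensity * atten[z]
      vox[z, , ] <- plane
    }
  }
  if (params$noise_sd > 0) {
    vox <- vox + withr::with_seed(derive_seed(params$rng_seed, 3),
      array(rnorm(length(vox), 0, params$noise_sd), dim = dim(vox)))
    vox[vox < 0] <- 0
  }
  list(
    stack = image_stack(vox, params$pixel_size_xy, params$z_step,
                        params$depth_of_first_plane),
    truth = list(
      somata = tibble::tibble(id = seq_len(params$n_somata),
                              z = centers[, "z"], y = centers[, "y"],
                              x = centers[, "x"], r_px = centers[, "r"]),
      plane_signal = tibble::tibble(
        depth_um = depths,
        expected_peak = params$background + params$soma_intensity * atten)
    ),
    params = params
  )
}

#' Simulate a single plane of planted bright discs
#'
#' Convenience generator for detector validation: `n_discs` non-overlapping
#' filled discs with radii uniform in `radius_range`, on a dark background,
#' with optional Gaussian noise.
#'
#' @param n_discs Number of discs.
#' @param shape Plane dimensions `c(ny, nx)`.
#' @param radius_range Radius range in pixels.
#' @param intensity Disc intensity, a.u.
#' @param background Background intensity, a.u.
#' @param noise_sd Additive Gaussian noise s.d., a.u.
#' @param rng_seed Integer seed.
#' @return A list with `plane` (matrix) and `truth` (tibble `y`, `x`, `r`).
#' @export
simulate_disc_plane <- function(n_discs = 20, shape = c(256, 256),
                                radius_range = c(6, 12), intensity = 100,
                                background = 0, noise_sd = 0, rng_seed = 1) {
  ny <- shape[1]; nx <- shape[2]
  pl <- withr::with_seed(as.integer(rng_seed), {
    cc <- place_centers(n_discs, ny, nx, radius_range[2],
                        2 * radius_range[2] + 2)
    r <- runif(n_discs, radius_range[1], radius_range[2])
    plane <- matrix(background, ny, nx)
    yy <- matrix(seq_len(ny), ny, nx)
    xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    for (s in seq_len(n_discs)) {
      plane[(yy - cc[s, "y"])^2 + (xx - cc[s, "x"])^2 <= r[s]^2] <- intensity
    }
    if (noise_sd > 0) {
      plane <- plane + matrix(rnorm(ny * nx, 0, noise_sd), ny, nx)
    }
    list(plane = plane,
         truth = tibble::tibble(y = cc[, "y"], x = cc[, "x"], r = r))
  })
  pl
}

#' Parameters for a synthetic conditioning session
#'
#' The defaults state the recording conditions the analysis assumes: 100
#' neurons imaged at 30 Hz over 30 water deliveries at 20 s intervals, a
#' red-GECI-like calcium kernel (0.1 s rise, 1.0 s decay), temporally tuned
#' transients with 30% of tuned neurons preferring the pre-reward period
#' (the remainder split 5:2 between the first and second post-reward 5 s,
#' matching the observed peak-time composition), slow multiplicative
#' baseline drift, additive noise at ~2% of baseline, and near-perfect
#' licking with ~230 ms median latency.
#'
#' @param n_neurons,n_trials Population and trial counts.
#' @param inter_delivery_interval Seconds between deliveries (default 20).
#' @param frame_rate Acquisition rate, Hz (30, before 3-frame averaging).
#' @param fraction_tuned Fraction of neurons with a consistent preferred
#'   time; the rest emit one transient per trial at a uniformly random time.
#' @param fraction_prereward_tuned Among tuned neurons, fraction preferring
#'   the pre-reward period \[-10, 0).  Planted by deterministic counts
#'   (`round(fraction * n_tuned)`) so the planted composition is exact.
#' @param post_early_weight Among post-reward-tuned neurons, probability
#'   mass on \[0, 5) versus \[5, 10).
#' @param tuning_width Gaussian s.d. of the within-trial activity bump, s.
#' @param sigma_t Trial-to-trial jitter s.d. of the bump centre, s.
#' @param amplitude Peak dF/F of a single transient.
#' @param rise_tau,decay_tau Calcium-kernel time constants, s.
#' @param baseline_level Baseline fluorescence, a.u.
#' @param drift_amplitude Sinusoidal drift amplitude as a fraction of
#'   baseline.
#' @param drift_period Drift period, s.
#' @param drift_linear Linear drift over the whole session as a fraction of
#'   baseline.
#' @param noise_sd Additive Gaussian noise s.d., a.u.
#' @param lick_latency_median Median first-lick latency, s.
#' @param lick_latency_sdlog Log-scale s.d. of the lognormal latency.
#' @param miss_probability Probability that a delivery elicits no licking.
#' @param spontaneous_lick_rate Poisson rate of task-unrelated licks, Hz.
#' @param rng_seed Integer seed.
#' @return A validated list of class `session_params`.
#' @export
session_params <- function(n_neurons = 100, n_trials = 30,
                           inter_delivery_interval = 20, frame_rate = 30,
                           fraction_tuned = 1, fraction_prereward_tuned = 0.3,
                           post_early_weight = 5 / 7,
                           tuning_width = 1, sigma_t = 0.5, amplitude = 1,
                           rise_tau = 0.1, decay_tau = 1,
                           baseline_level = 100, drift_amplitude = 0.1,
                           drift_period = 300, drift_linear = 0.05,
                           noise_sd = 2,
                           lick_latency_median = 0.23,
                           lick_latency_sdlog = 0.35,
                           miss_probability = 0.01,
                           spontaneous_lick_rate = 0.2,
                           rng_seed = 1) {
  check_number(n_neurons, "n_neurons", lower = 1)
  check_number(n_trials, "n_trials", lower = 1)
  check_number(fraction_tuned, "fraction_tuned", lower = 0, upper = 1)
  check_number(fraction_prereward_tuned, "fraction_prereward_tuned",
               lower = 0, upper = 1)
  check_number(tuning_width, "tuning_width", lower = 0)
  check_number(sigma_t, "sigma_t", lower = 0)
  check_number(rise_tau, "rise_tau", lower = 0, strict_lower = TRUE)
  check_number(decay_tau, "decay_tau", lower = 0, strict_lower = TRUE)
  check_number(miss_probability, "miss_probability", lower = 0, upper = 1)
  structure(
    list(n_neurons = as.integer(n_neurons), n_trials = as.integer(n_trials),
         inter_delivery_interval = inter_delivery_interval,
         frame_rate = frame_rate, fraction_tuned = fraction_tuned,
         fraction_prereward_tuned = fraction_prereward_tuned,
         post_early_weight = post_early_weight,
         tuning_width = tuning_width, sigma_t = sigma_t,
         amplitude = amplitude, rise_tau = rise_tau, decay_tau = decay_tau,
         baseline_level = baseline_level,
         drift_amplitude = drift_amplitude, drift_period = drift_period,
         drift_linear = drift_linear, noise_sd = noise_sd,
         lick_latency_median = lick_latency_median,
         lick_latency_sdlog = lick_latency_sdlog,
         miss_probability = miss_probability,
         spontaneous_lick_rate = spontaneous_lick_rate,
         rng_seed = as.integer(rng_seed)),
    class = "session_params"
  )
}

# Response template: Gaussian activity bump convolved with a normalised
# difference-of-exponentials calcium kernel, peak-aligned so the template
# maximum sits exactly at the planted preferred time.
response_template <- function(tuning_width, rise_tau, decay_tau, rate) {
  dt <- 1 / rate
  tk <- seq(0, 8 * decay_tau, by = dt)
  ker <- exp(-tk / decay_tau) - exp(-tk / rise_tau)
  if (tuning_width > 0) {
    tg <- seq(-4 * tuning_width, 4 * tuning_width, by = dt)
    g <- exp(-tg^2 / (2 * tuning_width^2))
    v <- as.numeric(stats::convolve(g, rev(ker), type = "open"))
    t0 <- tg[1] + tk[1]
  } else {
    v <- ker
    t0 <- tk[1]
  }
  v <- v / max(v)
  pk <- which.max(v)
  list(values = v, rel_times = t0 + (seq_along(v) - 1) * dt -
         (t0 + (pk - 1) * dt))
}

#' Simulate a periodic-reward conditioning session
#'
#' Generates raw fluorescence traces, behavioural events, and complete
#' ground truth for a head-fixed conditioning session with water deliveries
#' every `inter_delivery_interval` seconds.  Tuned neurons emit one
#' calcium transient per trial centred at their preferred time plus
#' trial-to-trial jitter; untuned neurons emit one transient at a uniform
#' random time per trial.  Transients ride multiplicatively on a slowly
#' drifting baseline with additive Gaussian noise:
#' `F(t) = B(t) * (1 + dff(t)) + noise`, where `B` combines the level, a
#' slow sinusoid and a linear term.  Licking follows each non-missed
#' delivery with a lognormal first-lick latency and a ~7 Hz burst.
#'
#' All randomness flows from `rng_seed` through named sub-streams (tuning
#' assignment, event jitter, noise, behaviour, drift phase), so outputs are
#' bit-identical under a fixed seed and components can be varied
#' independently.
#'
#' @param params A [session_params()] list.
#' @return A list with `traces` (a [fluorescence_traces()]), `events` (an
#'   [event_list()]), `truth` (list: `neurons` tibble with `neuron`,
#'   `tuned`, `preferred_time`; `events` tibble with per neuron x trial
#'   planted bump times), and `params`.
#' @export
simulate_session <- function(params = session_params()) {
  stopifnot(inherits(params, "session_params"))
  p <- params
  idi <- p$inter_delivery_interval
  deliveries <- idi * seq_len(p$n_trials)
  duration <- idi * p$n_trials + idi / 2
  nf <- as.integer(round(duration * p$frame_rate))
  tt <- (seq_len(nf) - 0.5) / p$frame_rate

  # --- tuning assignment (deterministic counts, shuffled order) ----------
  truth_neurons <- withr::with_seed(derive_seed(p$rng_seed, 1), {
    n_tuned <- round(p$fraction_tuned * p$n_neurons)
    tuned <- c(rep(TRUE, n_tuned), rep(FALSE, p$n_neurons - n_tuned))
    n_pre <- round(p$fraction_prereward_tuned * n_tuned)
    n_post <- n_tuned - n_pre
    n_early <- round(p$post_early_weight * n_post)
    pref <- rep(NA_real_, p$n_neurons)
    if (n_tuned > 0) {
      pref[seq_len(n_tuned)] <- c(
        runif(n_pre, -10, 0),
        runif(n_early, 0, 5),
        runif(n_post - n_early, 5, 10))
    }
    ord <- sample.int(p$n_neurons)
    tibble::tibble(neuron = sprintf("n%03d", seq_len(p$n_neurons)),
                   tuned = tuned[ord], preferred_time = pref[ord])
  })

  tmpl <- response_template(p$tuning_width, p$rise_tau, p$decay_tau,
                            p$frame_rate)
  tv <- tmpl$values * p$amplitude
  toff <- tmpl$rel_times[1]
  tl <- length(tv)

  # --- planted transients ------------------------------------------------
  ev <- withr::with_seed(derive_seed(p$rng_seed, 2), {
    purrr::map_dfr(seq_len(p$n_neurons), function(i) {
      mu <- if (truth_neurons$tuned[i]) {
        truth_neurons$preferred_time[i] + rnorm(p$n_trials, 0, p$sigma_t)
      } else {
        runif(p$n_trials, -10, 10)
      }
      tibble::tibble(neuron = truth_neurons$neuron[i],
                     trial = seq_len(p$n_trials),
                     delivery_time = deliveries,
                     bump_time = deliveries + mu)
    })
  })

  # Transients are confined to their own 20 s delivery cycle: template
  # samples falling outside the cycle window wrap around within it.  This
  # keeps every trial window self-contained (no bleed into the neighbouring
  # trial) and makes untuned activity cyclostationary on the delivery
  # period -- the null-hypothesis class the circular-shift statistic tests.
  W <- as.integer(round(idi * p$frame_rate))
  dff <- matrix(0, p$n_neurons, nf,
                dimnames = list(truth_neurons$neuron, NULL))
  for (k in seq_len(nrow(ev))) {
    i <- match(ev$neuron[k], truth_neurons$neuron)
    j0 <- as.integer(round((ev$bump_time[k] + toff) * p$frame_rate + 0.5))
    js <- j0:(j0 + tl - 1L)
    cs <- as.integer(round((ev$delivery_time[k] - idi / 2) * p$frame_rate)) + 1L
    js <- ((js - cs) %% W) + cs
    ok <- js >= 1L & js <= nf
    dff[i, js[ok]] <- dff[i, js[ok]] + tv[ok]
  }

  # --- baseline drift and noise -----------------------------------------
  phases <- withr::with_seed(derive_seed(p$rng_seed, 5),
                             runif(p$n_neurons, 0, 2 * pi))
  fvals <- matrix(0, p$n_neurons, nf)
  for (i in seq_len(p$n_neurons)) {
    B <- p$baseline_level *
      (1 + p$drift_amplitude * sin(2 * pi * tt / p$drift_period + phases[i]) +
         p$drift_linear * tt / duration)
    fvals[i, ] <- B * (1 + dff[i, ])
  }
  if (p$noise_sd > 0) {
    fvals <- fvals + withr::with_seed(derive_seed(p$rng_seed, 3),
      matrix(rnorm(length(fvals), 0, p$noise_sd), nrow(fvals), ncol(fvals)))
  }
  rownames(fvals) <- truth_neurons$neuron

  # --- licking -----------------------------------------------------------
  licks <- withr::with_seed(derive_seed(p$rng_seed, 4), {
    out <- numeric(0)
    for (d in deliveries) {
      if (runif(1) < p$miss_probability) next
      lat <- rlnorm(1, log(p$lick_latency_median), p$lick_latency_sdlog)
      burst <- d + lat + cumsum(c(0, abs(rnorm(14, 1 / 7, 0.03))))
      out <- c(out, burst[burst < d + lat + 2])
    }
    if (p$spontaneous_lick_rate > 0) {
      n_sp <- rpois(1, p$spontaneous_lick_rate * duration)
      out <- c(out, runif(n_sp, 0, duration))
    }
    sort(out)
  })

  list(
    traces = fluorescence_traces(fvals, frame_rate = p$frame_rate,
                                 start_time = 0),
    events = event_list(deliveries, licks),
    truth = list(neurons = truth_neurons, events = ev),
    params = p
  )
}
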