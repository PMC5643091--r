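#' Optical configuration for an underfilled-objective two-photon setup
#'
#' Bundles the quantities that determine the excitation numerical aperture
#' when the back aperture of a high-NA water-immersion objective is
#' deliberately underfilled by a diameter-narrowed laser beam, together with
#' the cranial-window geometry and laser power settings needed for the
#' clipping check and the per-pulse energy.
#'
#' Defaults describe a 25x NA 1.00 objective (14.4 mm back aperture)
#' underfilled with a 7.2 mm (1/e^2 width) beam from an 80 MHz laser at
#' 1100 nm, focused 1.2 mm below a cranial window of 0.75 mm aperture
#' radius, with water immersion (n = 1.33).
#'
#' @param objective_na Numerical aperture of the objective, in (0, 2].
#' @param back_aperture_diameter Back-aperture diameter, mm.
#' @param beam_width_1e2 1/e^2 width of the excitation beam at the back
#'   aperture, mm.  May exceed the back aperture (overfilled case).
#' @param immersion_index Refractive index of the immersion medium (>= 1).
#' @param window_aperture_radius Radius of the clear aperture of the cranial
#'   window, mm.
#' @param focal_depth Depth of the focal plane below the window, mm.
#' @param average_power Average laser power at the front aperture, mW.
#' @param repetition_rate Laser repetition rate, MHz.
#' @param wavelength Excitation wavelength, nm.
#'
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config()
#' effective_na(cfg)
#' @export
optical_config <- function(objective_na = 1.00,
                           back_aperture_diameter = 14.4,
                           beam_width_1e2 = 7.2,
                           immersion_index = 1.33,
                           window_aperture_radius = 0.75,
                           focal_depth = 1.2,
                           average_power = 180,
                           repetition_rate = 80,
                           wavelength = 1100) {
  check_number(objective_na, "objective_na", lower = 0, upper = 2,
               strict_lower = TRUE)
  check_number(back_aperture_diameter, "back_aperture_diameter", lower = 0,
               strict_lower = TRUE)
  check_number(beam_width_1e2, "beam_width_1e2", lower = 0,
               strict_lower = TRUE)
  check_number(immersion_index, "immersion_index", lower = 1)
  check_number(window_aperture_radius, "window_aperture_radius", lower = 0,
               strict_lower = TRUE)
  check_number(focal_depth, "focal_depth", lower = 0, strict_lower = TRUE)
  check_number(average_power, "average_power", lower = 0)
  check_number(repetition_rate, "repetition_rate", lower = 0,
               strict_lower = TRUE)
  check_number(wavelength, "wavelength", lower = 0, strict_lower = TRUE)
  structure(
    list(objective_na = objective_na,
         back_aperture_diameter = back_aperture_diameter,
         beam_width_1e2 = beam_width_1e2,
         immersion_index = immersion_index,
         window_aperture_radius = window_aperture_radius,
         focal_depth = focal_depth,
         average_power = average_power,
         repetition_rate = repetition_rate,
         wavelength = wavelength),
    class = "optical_config"
  )
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  objective NA %.2f, back aperture %.1f mm, beam (1/e^2) %.1f mm\n",
              x$objective_na, x$back_aperture_diameter, x$beam_width_1e2))
  cat(sprintf("  window radius %.2f mm at focal depth %.2f mm (n = %.2f)\n",
              x$window_aperture_radius, x$focal_depth, x$immersion_index))
  cat(sprintf("  %g mW at %g MHz, %g nm\n",
              x$average_power, x$repetition_rate, x$wavelength))
  invisible(x)
}

#' Effective excitation numerical aperture of an underfilled objective
#'
#' When the excitation beam underfills the back aperture, only the central
#' part of the objective's angular acceptance is used for excitation, so the
#' effective NA is the objective NA scaled by the beam-to-aperture diameter
#' ratio.  Overfilled beams are clamped to the aperture, so the result never
#' exceeds the objective NA.
#'
#' @param cfg An [optical_config()].
#' @return Effective NA (dimensionless scalar).
#' @examples
#' effective_na(optical_config(1.00, 14.4, 7.2))  # 0.5
#' @export
effective_na <- function(cfg) {
  stopifnot(inherits(cfg, "optical_config"))
  cfg$objective_na *
    min(cfg$beam_width_1e2, cfg$back_aperture_diameter) /
    cfg$back_aperture_diameter
}

#' Maximum NA not clipped by the cranial window
#'
#' The marginal excitation ray reaching a focus at depth `d` below a window
#' of clear radius `r` makes an angle `atan(r / d)` with the optical axis;
#' the corresponding NA in an immersion medium of index `n` is
#' `n * sin(atan(r / d))`.  An effective NA below this bound means the beam
#' passes the window unclipped.
#'
#' @inheritParams effective_na
#' @return Maximum unclipped NA (dimensionless scalar).
#' @examples
#' clipping_na_limit(optical_config())  # ~0.70
#' @export
clipping_na_limit <- function(cfg) {
  stopifnot(inherits(cfg, "optical_config"))
  cfg$immersion_index *
    sin(atan(cfg$window_aperture_radius / cfg$focal_depth))
}

#' Laser pulse energy
#'
#' Average power divided by repetition rate; with power in mW and rate in
#' MHz the result is directly in nJ per pulse.
#'
#' @inheritParams effective_na
#' @return Pulse energy in nJ.
#' @examples
#' pulse_energy(optical_config(average_power = 180, repetition_rate = 80))
#' @export
pulse_energy <- function(cfg) {
  stopifnot(inherits(cfg, "optical_config"))
  cfg$average_power / cfg$repetition_rate
}

#' Key-value optics report
#'
#' Computes effective NA, the window-clipping NA bound with a
#' clipped/unclipped verdict, and the pulse energy, at full precision plus
#' the rounded values used for reporting (NA to 2 decimals, pulse energy to
#' 1 decimal, half-up).
#'
#' @inheritParams effective_na
#' @return A tibble with columns `quantity`, `value`, `printed`, `unit`.
#' @export
optics_report <- function(cfg) {
  stopifnot(inherits(cfg, "optical_config"))
  na_eff <- effective_na(cfg)
  na_lim <- clipping_na_limit(cfg)
  ej <- pulse_energy(cfg)
  tibble::tibble(
    quantity = c("effective_na", "clipping_na_limit", "unclipped",
                 "pulse_energy"),
    value = c(na_eff, na_lim, as.numeric(na_eff < na_lim), ej),
    printed = c(format(round_half_up(na_eff, 2), nsmall = 2),
                format(round_half_up(na_lim, 2), nsmall = 2),
                ifelse(na_eff < na_lim, "unclipped", "clipped"),
                format(round_half_up(ej, 1), nsmall = 1)),
    unit = c("NA", "NA", "", "nJ")
  )
}
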