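#' Bright-fraction signal of an image plane
#'
#' Mean intensity of the brightest `fraction` of pixels, the per-plane
#' signal measure used for depth profiling: robust to the sparse spatial
#' coverage of labelled somata because only the top of the intensity
#' distribution is averaged.  `k = max(1, floor(fraction * n_pixels))`
#' values are taken from a descending sort; ties at the k-th value are
#' broken by taking exactly `k` values (the mean is unaffected among equal
#' values).
#'
#' @param plane Numeric matrix (or vector) of pixel intensities.
#' @param fraction Fraction of pixels to average, in (0, 1].  Default 0.001
#'   (the brightest 0.1%).
#' @return Mean of the k brightest pixel values.
#' @examples
#' bright_signal(matrix(c(rep(0, 990), rep(50, 10)), 10, 100), 0.01)
#' @export
bright_signal <- function(plane, fraction = 0.001) {
  if (length(plane) == 0L || !is.numeric(plane)) {
    stop_invalid("`plane` must be a non-empty numeric matrix")
  }
  check_number(fraction, "fraction", lower = 0, upper = 1, strict_lower = TRUE)
  v <- as.numeric(plane)
  k <- max(1L, floor(fraction * length(v)))
  mean(sort(v, decreasing = TRUE)[seq_len(k)])
}

#' Per-depth image-quality profiles of a stack
#'
#' Applies [bright_signal()] and [detect_circles()] to every plane of a
#' stack and attaches the depth coordinate, reproducing the Z profiles used
#' to compare underfilled and overfilled objective configurations (signal
#' from the brightest pixels, and number of detected circular somata, as a
#' function of imaging depth).
#'
#' @param stack An [image_stack()].
#' @inheritParams bright_signal
#' @inheritParams detect_circles
#' @return A tibble of class `depth_profile` with columns `depth_um`,
#'   `bright_signal`, `circle_count`.
#' @export
depth_profiles <- function(stack, fraction = 0.001, r_min = 6, r_max = 12,
                           sensitivity = 0.5) {
  stopifnot(inherits(stack, "image_stack"))
  depths <- plane_depths(stack)
  nz <- dim(stack$voxels)[1]
  rows <- purrr::map(seq_len(nz), function(z) {
    plane <- stack$voxels[z, , ]
    tryCatch(
      tibble::tibble(
        depth_um = depths[z],
        bright_signal = bright_signal(plane, fraction),
        circle_count = nrow(detect_circles(plane, r_min, r_max, sensitivity))
      ),
      deepcalseq_error = function(e) {
        stop_invalid(sprintf("plane %d: %s", z, conditionMessage(e)))
      }
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("depth_profile", class(out))
  out
}

#' Full width at half maximum of an intensity profile
#'
#' The baseline is the profile minimum (in vivo profiles carry a background
#' offset), the half-maximum level is midway between baseline and peak, and
#' the two crossings flanking the (unique) peak are located by linear
#' interpolation between adjacent samples.
#'
#' @param profile Numeric vector of intensity samples.
#' @param spacing Sample spacing in um.
#' @return FWHM in um.
#' @examples
#' x <- seq(-10, 10, by = 0.05)
#' profile_fwhm(exp(-x^2 / (2 * 2^2)), 0.05)  # ~4.71 = 2*sqrt(2*log(2))*2
#' @export
profile_fwhm <- function(profile, spacing) {
  if (length(profile) < 3L || !is.numeric(profile)) {
    stop_invalid("`profile` must be a numeric vector of length >= 3")
  }
  check_number(spacing, "spacing", lower = 0, strict_lower = TRUE)
  base <- min(profile)
  pk <- which.max(profile)
  if (profile[pk] <= base) stop_invalid("profile has no peak above baseline")
  half <- (profile[pk] + base) / 2

  cross <- function(side) {
    if (side == "left") idx <- rev(seq_len(pk - 1)) else
      idx <- seq.int(pk + 1, length.out = length(profile) - pk)
    for (i in idx) {
      if (profile[i] <= half) {
        j <- if (side == "left") i + 1L else i - 1L # neighbour nearer peak
        # interpolate between sample i (below half) and j (above half)
        frac <- (profile[j] - half) / (profile[j] - profile[i])
        return(j + frac * (i - j))
      }
    }
    abort(sprintf("no half-maximum crossing on the %s side", side),
          class = c("deepcalseq_not_measurable", "deepcalseq_error"))
  }
  (cross("right") - cross("left")) * spacing
}

#' Treated-to-contralateral ROI intensity ratio
#'
#' Mean intensity over the treated-side region of interest divided by the
#' mean over the mirror-position contralateral ROI; the normalisation used
#' to compare immunoreactivity between hemispheres while compensating for
#' per-slice signal dispersion.
#'
#' @param image Numeric intensity matrix.
#' @param roi_treated,roi_contralateral Logical masks of the same dimensions
#'   as `image` (or index vectors into it).
#' @return Dimensionless ratio.
#' @export
roi_intensity_ratio <- function(image, roi_treated, roi_contralateral) {
  if (length(image) == 0L || !is.numeric(image)) {
    stop_invalid("`image` must be a non-empty numeric matrix")
  }
  a <- image[roi_treated]
  b <- image[roi_contralateral]
  if (length(a) == 0L || length(b) == 0L) {
    stop_invalid("both ROI masks must select at least one pixel")
  }
  mb <- mean(b)
  if (mb == 0) stop_invalid("contralateral ROI mean is zero")
  mean(a) / mb
}
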