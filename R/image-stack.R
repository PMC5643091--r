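#' Three-dimensional image stack
#'
#' Container for an XYZ intensity volume with its spatial calibration.  The
#' voxel array is indexed `[z, y, x]`; the depth of plane `z` below the
#' cortical surface is `depth_of_first_plane + (z - 1) * z_step` (positive
#' downward).
#'
#' @param voxels Numeric 3-D array of non-negative finite intensities,
#'   indexed `[z, y, x]`.
#' @param pixel_size_xy Lateral pixel size, um/pixel.
#' @param z_step Axial step between planes, um.
#' @param depth_of_first_plane Depth of plane 1 below the surface, um.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_size_xy = 0.994, z_step = 2.5,
                        depth_of_first_plane = 0) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop_invalid("`voxels` must be a 3-D array indexed [z, y, x]")
  }
  if (any(dim(voxels) < 1L)) stop_invalid("all stack dimensions must be >= 1")
  if (!all(is.finite(voxels)) || any(voxels < 0)) {
    stop_invalid("voxel intensities must be finite and non-negative")
  }
  check_number(pixel_size_xy, "pixel_size_xy", lower = 0, strict_lower = TRUE)
  check_number(z_step, "z_step", lower = 0, strict_lower = TRUE)
  check_number(depth_of_first_plane, "depth_of_first_plane", lower = 0)
  structure(
    list(voxels = voxels, pixel_size_xy = pixel_size_xy, z_step = z_step,
         depth_of_first_plane = depth_of_first_plane),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> %d planes of %d x %d px (%.3f um/px), z step %.2f um, first plane at %.0f um\n",
    d[1], d[2], d[3], x$pixel_size_xy, x$z_step, x$depth_of_first_plane))
  invisible(x)
}

#' Depths of the planes of a stack
#' @param stack An [image_stack()].
#' @return Numeric vector of depths in um, one per plane.
#' @export
plane_depths <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  stack$depth_of_first_plane + (seq_len(dim(stack$voxels)[1]) - 1) * stack$z_step
}
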