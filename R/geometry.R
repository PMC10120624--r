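#' Acquisition geometry of one confocal stack
#'
#' Describes the voxel calibration and acquisition parameters of a single
#' 3-D image stack: XY frame size, number of z planes, pixel pitch, z step,
#' the section's measured (post-processing) tissue thickness and its original
#' cut thickness, and the per-channel exposure times.
#'
#' Defaults reproduce a spinning-disk acquisition of a 40-micron section:
#' 512 x 512 pixels spanning 55 x 55 um (pixel pitch 55/512 um) and a
#' 0.25 um z step. `measured_thickness` is the tissue thickness measured at
#' the site after immunohistochemistry; depths are later rescaled by
#' `original_thickness / measured_thickness` to correct shrinkage.
#'
#' @param nx,ny Frame size in pixels.
#' @param nz Number of z planes.
#' @param pixel_size_xy Pixel pitch in microns.
#' @param z_step z increment between planes in microns.
#' @param z_offset Raw depth (um) of the top of the stack below the tissue
#'   surface; 0 means the first plane sits at the surface. Lets an
#'   acquisition cover only the depth band of interest.
#' @param measured_thickness Measured tissue thickness at the site (um).
#' @param original_thickness Original section thickness (um), default 40.
#' @param exposure_times Named numeric vector of per-channel exposure times
#'   (ms), names `vglut1`, `cb1r`, `vgat`, `lipofuscin`.
#'
#' @return An object of class `stack_geometry`.
#' @examples
#' geom <- stack_geometry(nx = 64, ny = 64, nz = 44)
#' voxel_volume(geom)
#' @export
stack_geometry <- function(nx = 512L, ny = 512L, nz = 44L,
                           pixel_size_xy = 55 / 512, z_step = 0.25,
                           z_offset = 0,
                           measured_thickness = 28, original_thickness = 40,
                           exposure_times = c(vglut1 = 500, cb1r = 800,
                                              vgat = 500, lipofuscin = 300)) {
  g <- list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
            pixel_size_xy = pixel_size_xy, z_step = z_step,
            z_offset = z_offset,
            measured_thickness = measured_thickness,
            original_thickness = original_thickness,
            exposure_times = exposure_times)
  class(g) <- "stack_geometry"
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  probs <- character()
  if (any(c(g$nx, g$ny, g$nz) <= 0)) {
    probs <- c(probs, "stack dimensions nx, ny, nz must be positive")
  }
  if (!isTRUE(g$pixel_size_xy > 0)) probs <- c(probs, "pixel_size_xy must be > 0")
  if (!isTRUE(g$z_step > 0)) probs <- c(probs, "z_step must be > 0")
  if (!isTRUE((g$z_offset %||% 0) >= 0)) probs <- c(probs, "z_offset must be >= 0")
  if (!isTRUE(g$measured_thickness > 0) ||
      !isTRUE(g$measured_thickness <= g$original_thickness)) {
    probs <- c(probs,
               "measured_thickness must satisfy 0 < measured <= original")
  }
  if (!all(CHANNELS %in% names(g$exposure_times)) ||
      any(g$exposure_times[CHANNELS] <= 0)) {
    probs <- c(probs, "exposure_times must be positive and named for all four channels")
  }
  if (length(probs)) abort(c("invalid stack geometry", probs), class = "boutonquant_geometry_error")
  invisible(g)
}

#' @export
print.stack_geometry <- function(x, ...) {
  cat(sprintf("<stack_geometry> %d x %d x %d voxels, %.4f um XY pitch, %.2f um z step\n",
              x$nx, x$ny, x$nz, x$pixel_size_xy, x$z_step))
  cat(sprintf("  thickness %.1f um measured / %.1f um original (shrinkage factor %.3f)\n",
              x$measured_thickness, x$original_thickness,
              x$measured_thickness / x$original_thickness))
  invisible(x)
}

#' Physical volume of one voxel
#'
#' @param geometry A [stack_geometry()].
#' @return Voxel volume in cubic microns (`pixel_size_xy^2 * z_step`).
#' @examples
#' voxel_volume(stack_geometry()) # (55/512)^2 * 0.25
#' @export
voxel_volume <- function(geometry) {
  validate_geometry(geometry)
  geometry$pixel_size_xy^2 * geometry$z_step
}

# raw (uncorrected) depth of voxel centers below the tissue surface, um
plane_depths_um <- function(geometry) {
  (geometry$z_offset %||% 0) + (seq_len(geometry$nz) - 0.5) * geometry$z_step
}
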