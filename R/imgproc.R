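# Pre-segmentation image processing: exposure normalization, z shrinkage
# correction, and difference-of-Gaussians spot enhancement.

#' Difference-of-Gaussians enhancement parameters
#'
#' @param sigma_narrow,sigma_wide Gaussian widths in XY pixels (defaults 0.7
#'   and 2.0). The DoG band-passes spot-like structure between the two
#'   scales; `sigma_narrow < sigma_wide` is required.
#' @param reference_exposure Optional named per-channel reference exposure
#'   times (ms) for [normalize_exposure()]; `NULL` means use the maximum
#'   exposure observed in the cohort manifest.
#' @param dims `2` (default) applies the DoG slice-wise in XY; `3` uses an
#'   isotropic 3-D blur in voxel units.
#' @return An object of class `enhancement_params`.
#' @export
enhancement_params <- function(sigma_narrow = 0.7, sigma_wide = 2.0,
                               reference_exposure = NULL, dims = 2) {
  if (!(sigma_narrow > 0 && sigma_narrow < sigma_wide)) {
    abort("EnhancementParams: need 0 < sigma_narrow < sigma_wide",
          class = "boutonquant_param_error")
  }
  if (!dims %in% c(2, 3)) abort("dims must be 2 or 3", class = "boutonquant_param_error")
  structure(list(sigma_narrow = sigma_narrow, sigma_wide = sigma_wide,
                 reference_exposure = reference_exposure, dims = dims),
            class = "enhancement_params")
}

#' Normalize per-channel exposure times
#'
#' Rescales each channel by `reference_exposure / channel_exposure` so that
#' intensities from captures taken at different (optimal) exposures are
#' directly comparable. Linear in the input.
#'
#' @param stack 4-D array `[x, y, z, channel]` (or 3-D single channel).
#' @param exposure_times Named per-channel exposure times (ms) used at
#'   capture; a single number for a 3-D input.
#' @param reference_exposure Reference exposure(s), same shape as
#'   `exposure_times`.
#' @return The rescaled array.
#' @examples
#' x <- array(100, c(4, 4, 2, 4))
#' y <- normalize_exposure(x, c(vglut1 = 1000, cb1r = 500, vgat = 500,
#'                              lipofuscin = 500),
#'                         c(vglut1 = 500, cb1r = 500, vgat = 500,
#'                           lipofuscin = 500))
#' y[1, 1, 1, "vglut1"] # halved
#' @export
normalize_exposure <- function(stack, exposure_times, reference_exposure) {
  if (any(exposure_times <= 0) || any(reference_exposure <= 0)) {
    abort("exposure times must be positive", class = "boutonquant_param_error")
  }
  if (length(dim(stack)) == 3) {
    return(stack * (reference_exposure[[1]] / exposure_times[[1]]))
  }
  stopifnot(length(dim(stack)) == 4)
  chans <- dimnames(stack)[[4]] %||% names(exposure_times)
  for (k in seq_len(dim(stack)[4])) {
    ch <- chans[k]
    stack[, , , k] <- stack[, , , k] *
      (reference_exposure[[ch]] / exposure_times[[ch]])
  }
  stack
}

#' Correct z positions for tissue shrinkage
#'
#' Sections cut at `original_thickness` shrink during immunohistochemistry
#' to `measured_thickness`; depths measured in the shrunken tissue are
#' rescaled by `original / measured` so that depth filters apply on the
#' original-tissue scale.
#'
#' @param z_positions Raw depths below the tissue surface (um).
#' @param measured_thickness,original_thickness Thickness (um).
#' @return Corrected depths (um); order is preserved.
#' @examples
#' correct_z_shrinkage(8.4, 28, 40) # 12
#' @export
correct_z_shrinkage <- function(z_positions, measured_thickness,
                                original_thickness = 40) {
  if (!isTRUE(measured_thickness > 0) ||
      !isTRUE(measured_thickness <= original_thickness)) {
    abort("need 0 < measured_thickness <= original_thickness",
          class = "boutonquant_param_error")
  }
  z_positions * (original_thickness / measured_thickness)
}

#' Difference-of-Gaussians spot enhancement
#'
#' Computes `G(sigma_narrow) * I - G(sigma_wide) * I` for one channel,
#' applied slice-wise in XY by default (the band-pass that demarcates
#' punctate immunofluorescence for segmentation). Negative responses are
#' clipped to zero so downstream thresholds act on nonnegative data.
#'
#' @param channel 3-D numeric array (one channel).
#' @param params An [enhancement_params()].
#' @param clip Clip negative values at zero (default `TRUE`).
#' @return Enhanced array of the same shape.
#' @export
difference_of_gaussians <- function(channel, params = enhancement_params(),
                                    clip = TRUE) {
  if (!all(is.finite(channel))) {
    abort("channel contains non-finite voxels", class = "boutonquant_input_error")
  }
  d <- dim(channel)
  stopifnot(length(d) == 3)
  if (params$dims == 2) {
    # slice-wise XY band-pass: one filter2 pass per sigma over all frames
    brush <- function(sigma) {
      size <- 2 * ceiling(3 * sigma) + 1
      EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
    }
    out <- EBImage::filter2(channel, brush(params$sigma_narrow)) -
      EBImage::filter2(channel, brush(params$sigma_wide))
    out <- array(as.numeric(out), d)
  } else {
    out <- EBImage::gblur(channel, sigma = params$sigma_narrow) -
      EBImage::gblur(channel, sigma = params$sigma_wide)
  }
  if (clip) out[out < 0] <- 0
  out
}

#' Enhance all channels of a stack
#'
#' Convenience wrapper applying [difference_of_gaussians()] to each channel.
#'
#' @param stack 4-D array `[x, y, z, channel]`.
#' @param params An [enhancement_params()].
#' @return 4-D array of enhanced channels.
#' @export
enhance_stack <- function(stack, params = enhancement_params()) {
  out <- stack
  for (k in seq_len(dim(stack)[4])) {
    out[, , , k] <- difference_of_gaussians(stack[, , , k], params)
  }
  out
}
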