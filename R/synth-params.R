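#' Simulation parameters for synthetic cohorts
#'
#' Controls the generative model behind [generate_stack()] and
#' [generate_cohort()]: how many matched subject pairs, the group-level mean
#' CB1R intensity in each terminal-type cell (excitatory vGlut1 boutons and
#' the high/low modes of the inhibitory vGAT population), object densities,
#' lipofuscin contamination, noise, depth-dependent signal attenuation and
#' tissue shrinkage.
#'
#' Default cell means are the reference group means shipped with the package
#' (see [reference_group_means()]): Ctrl/SZ 770.537/1042.193 ADU for
#' excitatory boutons, 2510.098/2137.309 for high-expressing inhibitory and
#' 435.461/460.420 for low-expressing inhibitory boutons, so a default cohort
#' carries a +35.3% excitatory and a -14.9% high-inhibitory group effect.
#' Per-bouton intensities are lognormal about the cell mean
#' (`intensity_cv`), with one multiplicative lognormal scale per subject
#' (`subject_cv`) shared across that subject's boutons.
#'
#' @param n_pairs Number of matched Ctrl/SZ subject pairs.
#' @param vglut1_cb1r_mean,vgat_high_cb1r_mean,vgat_low_cb1r_mean Named
#'   numeric vectors `c(Ctrl = , SZ = )` of mean CB1R intensity (ADU) for the
#'   three terminal-type cells.
#' @param high_fraction Proportion of vGAT boutons drawn from the
#'   high-expressor mode.
#' @param intensity_cv Coefficient of variation of per-bouton CB1R intensity
#'   about its cell mean.
#' @param subject_cv Coefficient of variation of the per-subject
#'   multiplicative intensity scale. Together with `intensity_cv` the
#'   default keeps the control-median split point at least 3 combined
#'   standard deviations from both vGAT modes in both groups, so the
#'   high/low classes the split recovers coincide with the generating
#'   mixture components (see the vignette; this deliberately understates
#'   realistic between-subject spread).
#' @param densities_per_type Named vector of object densities per 1000 um^3
#'   for `vglut1`, `vgat` and `cb1r_only` (non-synaptic CB1R puncta).
#'   Defaults are deliberately sparse — far below real cortical bouton
#'   density — so that crowding (overlapping CB1R footprints of distinct
#'   objects under one mask) contaminates measured means by under ~2% and
#'   recovery of the generating intensities stays interpretable; see the
#'   vignette's crowding budget.
#' @param lipofuscin_density Lipofuscin blob density per 1000 um^3.
#' @param marker_amplitude Named vector, peak marker-channel amplitude (ADU)
#'   for vglut1 and vgat boutons.
#' @param marker_amplitude_cv CV of per-object marker amplitudes.
#' @param cb1r_only_amplitude,cb1r_only_cv Peak amplitude (ADU) and CV of
#'   non-synaptic CB1R puncta.
#' @param lipofuscin_amplitude Mean per-channel peak amplitude (ADU) of
#'   lipofuscin blobs (broad-spectrum: rendered into all four channels).
#' @param sigma_xy_range Range (um) of the lateral Gaussian width of puncta;
#'   axial width is `2 * sigma_xy` (post-deconvolution bouton scale, keeps
#'   objects inside the 0.03–2.0 um^3 size gate).
#' @param lipofuscin_sigma_range Range (um) of lipofuscin lateral widths.
#' @param noise List with `gaussian_sd` (ADU) and `poisson_scale`
#'   (unitless); per-voxel noise is Gaussian with variance
#'   `gaussian_sd^2 + poisson_scale * signal`.
#' @param depth_attenuation_rate Fractional signal loss per um of raw depth,
#'   referenced to the mid-depth of the analysis window (see vignette).
#' @param measured_thickness_range Range (um) of per-subject measured tissue
#'   thickness; shrinkage factor is `measured / original`.
#' @param exposure_jitter Range of multiplicative jitter on per-site optimal
#'   exposures (lipofuscin is always captured at its constant exposure).
#'
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_pairs = 10,
                       vglut1_cb1r_mean = c(Ctrl = 770.537, SZ = 1042.193),
                       vgat_high_cb1r_mean = c(Ctrl = 2510.098, SZ = 2137.309),
                       vgat_low_cb1r_mean = c(Ctrl = 435.461, SZ = 460.420),
                       high_fraction = 0.5,
                       intensity_cv = 0.10,
                       subject_cv = 0.05,
                       densities_per_type = c(vglut1 = 6, vgat = 12, cb1r_only = 5),
                       lipofuscin_density = 2,
                       marker_amplitude = c(vglut1 = 3000, vgat = 3000),
                       marker_amplitude_cv = 0.2,
                       cb1r_only_amplitude = 500,
                       cb1r_only_cv = 0.5,
                       lipofuscin_amplitude = 1200,
                       sigma_xy_range = c(0.15, 0.25),
                       lipofuscin_sigma_range = c(0.25, 0.5),
                       noise = list(gaussian_sd = 15, poisson_scale = 0.5),
                       depth_attenuation_rate = 0.02,
                       measured_thickness_range = c(26, 30),
                       exposure_jitter = c(0.8, 1.25)) {
  p <- list(n_pairs = n_pairs,
            vglut1_cb1r_mean = vglut1_cb1r_mean,
            vgat_high_cb1r_mean = vgat_high_cb1r_mean,
            vgat_low_cb1r_mean = vgat_low_cb1r_mean,
            high_fraction = high_fraction,
            intensity_cv = intensity_cv,
            subject_cv = subject_cv,
            densities_per_type = densities_per_type,
            lipofuscin_density = lipofuscin_density,
            marker_amplitude = marker_amplitude,
            marker_amplitude_cv = marker_amplitude_cv,
            cb1r_only_amplitude = cb1r_only_amplitude,
            cb1r_only_cv = cb1r_only_cv,
            lipofuscin_amplitude = lipofuscin_amplitude,
            sigma_xy_range = sigma_xy_range,
            lipofuscin_sigma_range = lipofuscin_sigma_range,
            noise = noise,
            depth_attenuation_rate = depth_attenuation_rate,
            measured_thickness_range = measured_thickness_range,
            exposure_jitter = exposure_jitter)
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  probs <- character()
  if (!isTRUE(p$n_pairs >= 1)) probs <- c(probs, "n_pairs must be >= 1")
  if (any(p$densities_per_type < 0) || p$lipofuscin_density < 0) {
    probs <- c(probs, "densities must be >= 0")
  }
  if (!isTRUE(p$high_fraction >= 0 && p$high_fraction <= 1)) {
    probs <- c(probs, "high_fraction must lie in [0, 1]")
  }
  for (nm in c("vglut1_cb1r_mean", "vgat_high_cb1r_mean", "vgat_low_cb1r_mean")) {
    if (!all(c("Ctrl", "SZ") %in% names(p[[nm]])) || any(p[[nm]] < 0)) {
      probs <- c(probs, sprintf("%s must be nonnegative and named Ctrl/SZ", nm))
    }
  }
  if (p$noise$gaussian_sd < 0 || p$noise$poisson_scale < 0) {
    probs <- c(probs, "noise parameters must be >= 0")
  }
  if (p$depth_attenuation_rate < 0) {
    probs <- c(probs, "depth_attenuation_rate must be >= 0")
  }
  if (length(probs)) abort(c("invalid sim_params", probs), class = "boutonquant_param_error")
  invisible(p)
}

#' Fractional laminar boundary scheme
#'
#' Cortical layer boundaries expressed as fractions of the pia-to-white-matter
#' distance: I `[0, 0.10)`, II `[0.10, 0.20)`, III `[0.20, 0.50)`,
#' IV `[0.50, 0.60)`, V `[0.60, 0.80)`, VI `[0.80, 1.0]`. The intervals
#' partition `[0, 1]`; sampling sites carry their layer label in the cohort
#' manifest rather than being re-derived from images.
#'
#' @return A tibble with columns `layer`, `lower`, `upper`.
#' @examples
#' layer_scheme()
#' @export
layer_scheme <- function() {
  tibble(layer = c("I", "II", "III", "IV", "V", "VI"),
         lower = c(0, 0.10, 0.20, 0.50, 0.60, 0.80),
         upper = c(0.10, 0.20, 0.50, 0.60, 0.80, 1.00))
}
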