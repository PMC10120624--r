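# Synthetic 4-channel stacks with ground truth.
#
# The generative model: boutons and non-synaptic CB1R puncta are anisotropic
# 3-D Gaussians (sigma_z = 2 sigma_xy, post-deconvolution scale); the CB1R
# signal *inside* a marker bouton is a uniform plateau over the bouton
# support (receptor fills the terminal), so the mean CB1R intensity under
# any mask contained in the bouton is a well-defined scalar ground truth.
# Lipofuscin blobs are larger Gaussians rendered into all four channels.
# Signal is attenuated with raw depth (antibody penetrance), referenced to
# the mid-depth of the 10-14 um analysis window, and per-voxel
# Poisson-Gaussian noise is added last.

NOMINAL_EXPOSURE <- c(vglut1 = 500, cb1r = 800, vgat = 500, lipofuscin = 300)

# receptor plateau support (sigma-normalized radius) and edge softness;
# wide enough that segmentation masks of bright boutons stay inside the
# uniform region, so mask means equal the plateau value
PLATEAU_RADIUS <- 2.25
PLATEAU_EDGE_SD <- 0.35

# raw-depth reference for attenuation: corrected mid-window depth (12 um)
# mapped back to raw depth for this section's shrinkage
attenuation_profile <- function(geometry, rate) {
  z_ref <- 12 * geometry$measured_thickness / geometry$original_thickness
  exp(-rate * (plane_depths_um(geometry) - z_ref))
}

lognormal_draw <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# draw ground-truth objects for one stack (rng state must already be set)
draw_truth_objects <- function(geometry, params, group, subject_scale) {
  fov <- c(geometry$nx * geometry$pixel_size_xy,
           geometry$ny * geometry$pixel_size_xy,
           geometry$nz * geometry$z_step)
  vol_1000 <- prod(fov) / 1000

  z0 <- geometry$z_offset %||% 0
  one_role <- function(role, n) {
    if (n == 0) return(NULL)
    sxy <- runif(n, params$sigma_xy_range[1], params$sigma_xy_range[2])
    tibble(channel_role = role,
           x_um = runif(n, 0, fov[1]), y_um = runif(n, 0, fov[2]),
           z_um = z0 + runif(n, 0, fov[3]),
           sigma_xy_um = sxy, sigma_z_um = 2 * sxy,
           amp_vglut1 = 0, amp_cb1r = 0, amp_vgat = 0, amp_lipofuscin = 0,
           cb1r_mean_truth = NA_real_, expressor_truth = NA_character_)
  }

  dens <- params$densities_per_type
  counts <- rpois(4, c(dens[["vglut1"]], dens[["vgat"]], dens[["cb1r_only"]],
                       params$lipofuscin_density) * vol_1000)
  tr <- bind_rows(one_role("vglut1", counts[1]), one_role("vgat", counts[2]),
                  one_role("cb1r_only", counts[3]),
                  one_role("lipofuscin", counts[4]))
  if (is.null(tr) || nrow(tr) == 0) {
    return(tibble(object_id = integer(), channel_role = character(),
                  x_um = double(), y_um = double(), z_um = double(),
                  sigma_xy_um = double(), sigma_z_um = double(),
                  amp_vglut1 = double(), amp_cb1r = double(),
                  amp_vgat = double(), amp_lipofuscin = double(),
                  cb1r_mean_truth = double(), expressor_truth = character()))
  }

  is_vglut1 <- tr$channel_role == "vglut1"
  is_vgat <- tr$channel_role == "vgat"
  is_cb1r <- tr$channel_role == "cb1r_only"
  is_lipo <- tr$channel_role == "lipofuscin"

  tr$amp_vglut1[is_vglut1] <- lognormal_draw(sum(is_vglut1),
                                             params$marker_amplitude[["vglut1"]],
                                             params$marker_amplitude_cv)
  tr$amp_vgat[is_vgat] <- lognormal_draw(sum(is_vgat),
                                         params$marker_amplitude[["vgat"]],
                                         params$marker_amplitude_cv)

  # per-bouton CB1R plateau values from the group's terminal-type cells
  if (any(is_vglut1)) {
    m <- params$vglut1_cb1r_mean[[group]] * subject_scale
    tr$amp_cb1r[is_vglut1] <- lognormal_draw(sum(is_vglut1), m, params$intensity_cv)
  }
  if (any(is_vgat)) {
    n_vgat <- sum(is_vgat)
    hi <- runif(n_vgat) < params$high_fraction
    tr$expressor_truth[is_vgat] <- ifelse(hi, "high", "low")
    m_hi <- params$vgat_high_cb1r_mean[[group]] * subject_scale
    m_lo <- params$vgat_low_cb1r_mean[[group]] * subject_scale
    vals <- numeric(n_vgat)
    vals[hi] <- lognormal_draw(sum(hi), m_hi, params$intensity_cv)
    vals[!hi] <- lognormal_draw(sum(!hi), m_lo, params$intensity_cv)
    tr$amp_cb1r[is_vgat] <- vals
  }
  if (any(is_cb1r)) {
    tr$amp_cb1r[is_cb1r] <- lognormal_draw(sum(is_cb1r),
                                           params$cb1r_only_amplitude,
                                           params$cb1r_only_cv)
  }
  if (any(is_lipo)) {
    n_l <- sum(is_lipo)
    sl <- runif(n_l, params$lipofuscin_sigma_range[1], params$lipofuscin_sigma_range[2])
    tr$sigma_xy_um[is_lipo] <- sl
    tr$sigma_z_um[is_lipo] <- 2 * sl
    for (ch in CHANNELS) {
      tr[[paste0("amp_", ch)]][is_lipo] <-
        params$lipofuscin_amplitude * runif(n_l, 0.5, 1.5)
    }
  }

  tr$object_id <- seq_len(nrow(tr))
  dplyr::relocate(tr, "object_id")
}

# add one object's footprint into a 3-D channel array (modified in place by
# the caller via returned array); profile: "gaussian" or "plateau"
add_footprint <- function(arr, geometry, x0, y0, z0, sx, sz, amp, profile) {
  px <- geometry$pixel_size_xy; zs <- geometry$z_step
  zoff <- geometry$z_offset %||% 0
  zl <- z0 - zoff   # center in stack-local z (um)
  reach_xy <- 4 * sx; reach_z <- 4 * sz
  rng <- function(lo, hi, nmax) {
    a <- max(1L, as.integer(floor(lo))); b <- min(nmax, as.integer(ceiling(hi)))
    if (b < a) integer() else a:b
  }
  ix <- rng((x0 - reach_xy) / px, (x0 + reach_xy) / px, geometry$nx)
  iy <- rng((y0 - reach_xy) / px, (y0 + reach_xy) / px, geometry$ny)
  iz <- rng((zl - reach_z) / zs, (zl + reach_z) / zs, geometry$nz)
  if (!length(ix) || !length(iy) || !length(iz)) return(arr)
  dx <- ((ix - 0.5) * px - x0) / sx
  dy <- ((iy - 0.5) * px - y0) / sx
  dz <- ((iz - 0.5) * zs - zl) / sz
  r2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  if (profile == "gaussian") {
    val <- amp * exp(-r2 / 2)
  } else { # plateau: uniform core, Gaussian edge beyond the support radius
    r <- sqrt(r2)
    val <- amp * ifelse(r <= PLATEAU_RADIUS, 1,
                        exp(-(r - PLATEAU_RADIUS)^2 / (2 * PLATEAU_EDGE_SD^2)))
  }
  arr[ix, iy, iz] <- arr[ix, iy, iz] + val
  arr
}

# noise-free scene (with depth attenuation) at nominal exposure
render_scene <- function(truth, geometry, params) {
  empty <- array(0, c(geometry$nx, geometry$ny, geometry$nz))
  chans <- setNames(rep(list(empty), 4), CHANNELS)
  for (i in seq_len(nrow(truth))) {
    o <- truth[i, ]
    role <- o$channel_role
    if (role == "vglut1") {
      chans$vglut1 <- add_footprint(chans$vglut1, geometry, o$x_um, o$y_um, o$z_um,
                                    o$sigma_xy_um, o$sigma_z_um, o$amp_vglut1, "gaussian")
      chans$cb1r <- add_footprint(chans$cb1r, geometry, o$x_um, o$y_um, o$z_um,
                                  o$sigma_xy_um, o$sigma_z_um, o$amp_cb1r, "plateau")
    } else if (role == "vgat") {
      chans$vgat <- add_footprint(chans$vgat, geometry, o$x_um, o$y_um, o$z_um,
                                  o$sigma_xy_um, o$sigma_z_um, o$amp_vgat, "gaussian")
      chans$cb1r <- add_footprint(chans$cb1r, geometry, o$x_um, o$y_um, o$z_um,
                                  o$sigma_xy_um, o$sigma_z_um, o$amp_cb1r, "plateau")
    } else if (role == "cb1r_only") {
      chans$cb1r <- add_footprint(chans$cb1r, geometry, o$x_um, o$y_um, o$z_um,
                                  o$sigma_xy_um, o$sigma_z_um, o$amp_cb1r, "gaussian")
    } else if (role == "lipofuscin") {
      for (ch in CHANNELS) {
        a <- o[[paste0("amp_", ch)]]
        if (a > 0) chans[[ch]] <- add_footprint(chans[[ch]], geometry, o$x_um,
                                                o$y_um, o$z_um, o$sigma_xy_um,
                                                o$sigma_z_um, a, "gaussian")
      }
    }
  }
  attn <- attenuation_profile(geometry, params$depth_attenuation_rate)
  stack <- array(0, c(geometry$nx, geometry$ny, geometry$nz, 4),
                 dimnames = list(NULL, NULL, NULL, CHANNELS))
  for (k in seq_along(CHANNELS)) {
    ch <- chans[[CHANNELS[k]]]
    for (iz in seq_len(geometry$nz)) ch[, , iz] <- ch[, , iz] * attn[iz]
    stack[, , , k] <- ch
  }
  stack
}

#' Build a ground-truth object row by hand
#'
#' Constructs a single ground-truth object (one row of the truth-table
#' schema) for controlled scenes: place a bouton, a non-synaptic CB1R
#' punctum or a lipofuscin blob at exact coordinates with exact
#' amplitudes, then render with [render_truth()].
#'
#' @param channel_role `"vglut1"`, `"vgat"`, `"cb1r_only"` or
#'   `"lipofuscin"`.
#' @param x_um,y_um,z_um Center coordinates (um; z is raw depth below the
#'   surface).
#' @param sigma_xy_um Lateral Gaussian width (um); axial width defaults to
#'   twice this.
#' @param sigma_z_um Axial width (um).
#' @param marker_amp Peak marker-channel amplitude (ADU) for bouton roles.
#' @param cb1r_value CB1R plateau value (bouton roles) or Gaussian peak
#'   (`cb1r_only`), ADU.
#' @param lipofuscin_amp Per-channel peak amplitude for `lipofuscin`
#'   (recycled to 4 channels).
#' @return A one-row truth tibble.
#' @export
truth_object <- function(channel_role, x_um, y_um, z_um, sigma_xy_um = 0.25,
                         sigma_z_um = 2 * sigma_xy_um, marker_amp = 3000,
                         cb1r_value = 800, lipofuscin_amp = 1500) {
  stopifnot(channel_role %in% c("vglut1", "vgat", "cb1r_only", "lipofuscin"))
  tr <- tibble(object_id = 1L, channel_role = channel_role,
               x_um = x_um, y_um = y_um, z_um = z_um,
               sigma_xy_um = sigma_xy_um, sigma_z_um = sigma_z_um,
               amp_vglut1 = 0, amp_cb1r = 0, amp_vgat = 0,
               amp_lipofuscin = 0, cb1r_mean_truth = NA_real_,
               expressor_truth = NA_character_)
  if (channel_role == "vglut1") {
    tr$amp_vglut1 <- marker_amp; tr$amp_cb1r <- cb1r_value
  } else if (channel_role == "vgat") {
    tr$amp_vgat <- marker_amp; tr$amp_cb1r <- cb1r_value
  } else if (channel_role == "cb1r_only") {
    tr$amp_cb1r <- cb1r_value
  } else {
    amps <- rep_len(lipofuscin_amp, 4)
    tr$amp_vglut1 <- amps[1]; tr$amp_cb1r <- amps[2]
    tr$amp_vgat <- amps[3]; tr$amp_lipofuscin <- amps[4]
  }
  tr
}

#' Render a ground-truth table into a noise-free stack
#'
#' The deterministic half of [generate_stack()]: renders the given objects
#' (with depth attenuation per `params`, no noise, nominal exposure).
#'
#' @param truth A truth tibble ([truth_object()] rows or a
#'   [generate_stack()] truth table).
#' @param geometry A [stack_geometry()].
#' @param params A [sim_params()] (only the attenuation rate is used).
#' @return 4-D array `[x, y, z, channel]`.
#' @export
render_truth <- function(truth, geometry, params = sim_params()) {
  validate_geometry(geometry)
  render_scene(truth, geometry, params)
}

#' Generate one synthetic 4-channel stack with ground truth
#'
#' Renders a random scene of vGlut1/vGAT boutons, non-synaptic CB1R puncta
#' and lipofuscin blobs into a 4-channel voxel array (`[x, y, z, channel]`,
#' channels `vglut1`, `cb1r`, `vgat`, `lipofuscin`), applies per-channel
#' exposure scaling (from `geometry$exposure_times` relative to the nominal
#' exposures), depth attenuation and Poisson-Gaussian noise, and returns the
#' exact per-object ground-truth table.
#'
#' `cb1r_mean_truth` in the truth table is the noise-free mean CB1R
#' intensity a perfect bouton mask would measure (the plateau value times
#' the attenuation factor at the bouton center), at nominal exposure.
#'
#' @param geometry A [stack_geometry()] (carries the site's actual exposure
#'   times).
#' @param params A [sim_params()].
#' @param group `"Ctrl"` or `"SZ"`; selects the generating cell means.
#' @param subject_scale Multiplicative subject-level intensity scale.
#' @param layer_label,site_id Labels copied into the truth table.
#' @param seed Optional integer seed (set for reproducible stacks).
#' @param noise If `FALSE`, skip the noise step (scene stays exact).
#'
#' @return A list with elements `stack` (4-D numeric array of ADU) and
#'   `truth` (tibble of ground-truth objects).
#' @examples
#' g <- stack_geometry(nx = 48, ny = 48, nz = 24)
#' s <- generate_stack(g, sim_params(), seed = 1)
#' dim(s$stack); nrow(s$truth)
#' @export
generate_stack <- function(geometry, params = sim_params(), group = "Ctrl",
                           subject_scale = 1, layer_label = "III",
                           site_id = "site1", seed = NULL, noise = TRUE) {
  validate_geometry(geometry)
  validate_sim_params(params)
  stopifnot(group %in% c("Ctrl", "SZ"))
  if (!is.null(seed)) set.seed(seed)

  truth <- draw_truth_objects(geometry, params, group, subject_scale)
  stack <- render_scene(truth, geometry, params)

  if (nrow(truth)) {
    attn <- attenuation_profile(geometry, params$depth_attenuation_rate)
    iz_c <- pmin(pmax(ceiling((truth$z_um - (geometry$z_offset %||% 0)) /
                                geometry$z_step), 1L), geometry$nz)
    marker <- truth$channel_role %in% c("vglut1", "vgat")
    truth$cb1r_mean_truth[marker] <- truth$amp_cb1r[marker] * attn[iz_c[marker]]
  }
  truth$layer <- layer_label
  truth$site_id <- site_id

  # exposure scaling, then shot + read noise
  expo <- geometry$exposure_times[CHANNELS] / NOMINAL_EXPOSURE[CHANNELS]
  for (k in seq_along(CHANNELS)) {
    ch <- stack[, , , k] * expo[k]
    if (noise) {
      sdv <- sqrt(params$noise$gaussian_sd^2 + params$noise$poisson_scale * ch)
      if (any(sdv > 0)) ch <- ch + rnorm(length(ch), 0, sdv)
      ch[ch < 0] <- 0
    }
    stack[, , , k] <- ch
  }
  list(stack = stack, truth = truth)
}

#' Truth-derived voxel mask of one object
#'
#' The "perfect" mask of a ground-truth bouton: all voxels whose center lies
#' within the support ellipsoid `r <= radius` in sigma-normalized units.
#' Used as the oracle mask when validating segmentation and intensity
#' measurement.
#'
#' @param object One row of a ground-truth table.
#' @param geometry The stack's [stack_geometry()].
#' @param radius Support radius in sigma units (default: the plateau
#'   support radius).
#' @return Logical 3-D array.
#' @export
truth_mask <- function(object, geometry, radius = PLATEAU_RADIUS) {
  px <- geometry$pixel_size_xy; zs <- geometry$z_step
  dx <- (((seq_len(geometry$nx)) - 0.5) * px - object$x_um) / object$sigma_xy_um
  dy <- (((seq_len(geometry$ny)) - 0.5) * px - object$y_um) / object$sigma_xy_um
  dz <- (plane_depths_um(geometry) - object$z_um) / object$sigma_z_um
  r2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  r2 <= radius^2
}
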