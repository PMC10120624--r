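# Shared fixtures and independent oracles.

# small acquisition covering the full corrected 10-14 um window
small_geom <- function(nx = 64, ny = 64, nz = 18, measured = 28, ...) {
  stack_geometry(nx = nx, ny = ny, nz = nz, z_offset = 6,
                 measured_thickness = measured, ...)
}

# noise- and attenuation-free parameters with nothing in the scene unless
# asked for
clean_params <- function(...) {
  args <- utils::modifyList(
    list(densities_per_type = c(vglut1 = 0, vgat = 0, cb1r_only = 0),
         lipofuscin_density = 0,
         noise = list(gaussian_sd = 0, poisson_scale = 0),
         depth_attenuation_rate = 0),
    list(...))
  do.call(sim_params, args)
}

# brute-force Otsu: exhaustive search over every integer gray level,
# maximizing between-class variance of x < t vs x >= t (lowest t on ties)
otsu_brute <- function(x) {
  v <- floor(as.numeric(x))
  best <- -Inf; best_t <- NA
  for (t in (min(v) + 1):max(v)) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (!length(lo) || !length(hi)) next
    bcv <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (bcv > best * (1 + 1e-12)) { best <- bcv; best_t <- t }
  }
  best_t
}

# textbook pooled-variance two-sample t statistic
pooled_t_brute <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# two-sided Fisher p by exhaustive enumeration of hypergeometric tables
fisher_brute <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c
  support <- max(0, k - n2):min(n1, k)
  probs <- dhyper(support, n1, n2, k)
  sum(probs[probs <= dhyper(a, n1, n2, k) * (1 + 1e-7)])
}

# Hand-built micro-stack: four CB1R puncta, one vGlut1 punctum and one
# vGAT punctum arranged so the four marker-overlap combinations all occur.
overlap_fixture <- function() {
  g <- small_geom(nx = 96, ny = 96, nz = 18)
  p <- clean_params()
  z <- 8.4  # corrected depth 12 um at measured 28
  truth <- dplyr::bind_rows(
    truth_object("cb1r_only", 2.0, 2.0, z, 0.2, cb1r_value = 900), # alone
    truth_object("cb1r_only", 4.0, 4.0, z, 0.2, cb1r_value = 900), # + vglut1
    truth_object("cb1r_only", 6.0, 6.0, z, 0.2, cb1r_value = 900), # + vgat
    truth_object("cb1r_only", 8.0, 8.0, z, 0.2, cb1r_value = 900), # + both
    truth_object("vglut1", 4.0, 4.0, z, 0.2, cb1r_value = 700),
    truth_object("vgat", 6.0, 6.0, z, 0.2, cb1r_value = 700),
    truth_object("vglut1", 8.0, 8.0, z, 0.2, cb1r_value = 700),
    truth_object("vgat", 8.05, 8.0, z, 0.2, cb1r_value = 700))
  st <- render_truth(truth, g, p)
  seg_of <- function(ch) {
    segment_channel(difference_of_gaussians(st[, , , ch]), st[, , , ch],
                    geometry = g, channel = ch)
  }
  list(g = g, st = st, cb1r = seg_of("cb1r"), vglut1 = seg_of("vglut1"),
       vgat = seg_of("vgat"))
}

# match segmented objects to truth rows by centroid distance
match_objects <- function(truth, objects, tol = 0.3) {
  if (!nrow(truth) || !nrow(objects)) {
    return(list(recall = ifelse(nrow(truth) == 0, NA, 0),
                n_matched_truth = 0, n_false = nrow(objects)))
  }
  d <- sqrt(outer(truth$x_um, objects$x_um, "-")^2 +
              outer(truth$y_um, objects$y_um, "-")^2 +
              outer(truth$z_um, objects$z_um, "-")^2)
  list(n_truth = nrow(truth), n_obj = nrow(objects),
       n_matched_truth = sum(apply(d, 1, min) <= tol),
       n_false = sum(apply(d, 2, min) > tol))
}
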