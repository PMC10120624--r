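# Cohort-level simulation: matched pairs, manifests, reproducible per-site
# stacks, and a table-level shortcut for purely statistical simulations.

truncnorm1 <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Simulate a matched-pair cohort of image stacks
#'
#' Builds the cohort manifest for `n_pairs` matched Ctrl/SZ subject pairs,
#' each sampled at `sites_per_layer` sites in every requested cortical
#' layer. Subject covariates (sex, race, age, postmortem interval, storage
#' time, cannabis and antipsychotic exposure) are drawn from distributions
#' matching a middle-aged, predominantly male postmortem cohort; pair
#' members share sex and approximate age. Each site row carries its own
#' seed, measured tissue thickness and jittered per-channel exposure times
#' (lipofuscin always at its constant exposure), so any site's stack can be
#' regenerated independently with [generate_site()].
#'
#' Stacks are not rendered up front (a full cohort is hundreds of stacks);
#' use [generate_site()] to realize them, or pass `out_dir` to write every
#' site as a multi-page TIFF plus truth/manifest CSVs.
#'
#' @param params A [sim_params()].
#' @param geometry Base [stack_geometry()]; per-site thickness/exposures
#'   override its values.
#' @param layers Character vector of layer labels to sample.
#' @param sites_per_layer Sites per layer per subject.
#' @param seed Integer master seed.
#' @param noise Passed to [generate_stack()] when sites are realized.
#' @param out_dir Optional directory; if given, all stacks and tables are
#'   written there (see [write_cohort()]).
#'
#' @return An object of class `synthetic_cohort`: a list with `manifest`
#'   (tibble, one row per site), `params`, `geometry`, `noise`.
#' @examples
#' co <- generate_cohort(sim_params(n_pairs = 2),
#'                       stack_geometry(nx = 48, ny = 48, nz = 24),
#'                       layers = "III", sites_per_layer = 1, seed = 1)
#' nrow(co$manifest) # 2 pairs x 2 subjects x 1 layer x 1 site
#' @export
generate_cohort <- function(params = sim_params(), geometry = stack_geometry(),
                            layers = layer_scheme()$layer, sites_per_layer = 6,
                            seed = 1, noise = TRUE, out_dir = NULL) {
  validate_sim_params(params)
  validate_geometry(geometry)
  if (length(layers) == 0) {
    abort("at least one layer must be sampled", class = "boutonquant_param_error")
  }
  set.seed(seed)
  n_pairs <- params$n_pairs

  # pair-matched covariates
  pair_age <- truncnorm1(n_pairs, 47, 14, 22, 75)
  pair_sex <- c("F", rep("M", max(0, n_pairs - 1)))[seq_len(n_pairs)]
  subjects <- tidyr::expand_grid(pair_id = seq_len(n_pairs),
                                 group = c("Ctrl", "SZ")) |>
    mutate(subject_id = sprintf("%s%02d", ifelse(.data$group == "Ctrl", "C", "S"),
                                .data$pair_id),
           sex = pair_sex[.data$pair_id],
           age = round(pair_age[.data$pair_id] + rnorm(n(), 0, 2), 1),
           race = sample(c("White", "Black"), n(), replace = TRUE,
                         prob = c(0.85, 0.15)),
           pmi_hr = round(truncnorm1(n(), 19, 8, 4, 45), 1),
           storage_months = round(truncnorm1(n(), 188, 20, 120, 260), 1),
           cannabis_use = .data$group == "SZ" & runif(n()) < 0.3,
           antipsychotic_exposure = .data$group == "SZ" & runif(n()) < 0.8,
           measured_thickness = round(runif(n(), params$measured_thickness_range[1],
                                            params$measured_thickness_range[2]), 1),
           truth_subject_scale = lognormal_draw(n(), 1, params$subject_cv))

  manifest <- tidyr::expand_grid(subjects, layer = layers,
                                 site = seq_len(sites_per_layer)) |>
    mutate(site_id = sprintf("%s_L%s_s%d", .data$subject_id, .data$layer, .data$site),
           site_seed = sample.int(.Machine$integer.max - 1L, n()),
           exposure_vglut1 = round(NOMINAL_EXPOSURE[["vglut1"]] *
                                     runif(n(), params$exposure_jitter[1],
                                           params$exposure_jitter[2])),
           exposure_cb1r = round(NOMINAL_EXPOSURE[["cb1r"]] *
                                   runif(n(), params$exposure_jitter[1],
                                         params$exposure_jitter[2])),
           exposure_vgat = round(NOMINAL_EXPOSURE[["vgat"]] *
                                   runif(n(), params$exposure_jitter[1],
                                         params$exposure_jitter[2])),
           exposure_lipofuscin = NOMINAL_EXPOSURE[["lipofuscin"]]) |>
    select(-"site") |>
    dplyr::relocate("site_id", "subject_id", "pair_id", "group", "layer")

  cohort <- structure(list(manifest = manifest, params = params,
                           geometry = geometry, noise = noise, seed = seed),
                      class = "synthetic_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<synthetic_cohort> %d subjects (%d pairs), %d sites, layers: %s\n",
              dplyr::n_distinct(m$subject_id), dplyr::n_distinct(m$pair_id),
              nrow(m), paste(unique(m$layer), collapse = ", ")))
  invisible(x)
}

#' Realize one site of a synthetic cohort
#'
#' Regenerates the stack and ground-truth table for a single manifest row,
#' reproducibly from the row's own seed.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param site_id A `site_id` present in the manifest (or a row index).
#' @return A list: `stack`, `truth`, `geometry` (site-specific), `info`
#'   (the manifest row).
#' @export
generate_site <- function(cohort, site_id) {
  m <- cohort$manifest
  row <- if (is.numeric(site_id)) m[site_id, ] else m[m$site_id == site_id, ]
  if (nrow(row) != 1) {
    abort(sprintf("site '%s' not found in manifest", site_id),
          class = "boutonquant_param_error")
  }
  g <- cohort$geometry
  g$measured_thickness <- row$measured_thickness
  g$exposure_times <- c(vglut1 = row$exposure_vglut1, cb1r = row$exposure_cb1r,
                        vgat = row$exposure_vgat,
                        lipofuscin = row$exposure_lipofuscin)
  out <- generate_stack(g, cohort$params, group = row$group,
                        subject_scale = row$truth_subject_scale,
                        layer_label = row$layer, site_id = row$site_id,
                        seed = row$site_seed, noise = cohort$noise)
  list(stack = out$stack, truth = out$truth, geometry = g, info = row)
}

#' Simulate subject x layer x terminal-type measurement tables directly
#'
#' A table-level shortcut that draws the layer-aggregated mean-CB1R
#' measurements from the same statistical model the image generator
#' implements (subject scale, per-bouton lognormal spread averaged over
#' boutons and sites), skipping image rendering entirely. Used for
#' calibration studies of the statistics layer (e.g. null rejection rates
#' over hundreds of replicates) where rendering adds nothing.
#'
#' @param params A [sim_params()].
#' @param layers Layer labels.
#' @param sites_per_layer Sites averaged per layer.
#' @param n_boutons_per_site Named vector: boutons contributing to each
#'   site-level type mean (`vglut1`, `vgat_high`, `vgat_low`).
#' @param seed Integer seed.
#' @return A tibble with columns `subject_id`, `pair_id`, `group`, `layer`,
#'   `type`, `value`, plus subject covariates.
#' @export
sim_measurement_table <- function(params = sim_params(),
                                  layers = layer_scheme()$layer,
                                  sites_per_layer = 6,
                                  n_boutons_per_site = c(vglut1 = 8,
                                                         vgat_high = 4,
                                                         vgat_low = 4),
                                  seed = 1) {
  validate_sim_params(params)
  set.seed(seed)
  n_pairs <- params$n_pairs
  subjects <- tidyr::expand_grid(pair_id = seq_len(n_pairs),
                                 group = c("Ctrl", "SZ")) |>
    mutate(subject_id = sprintf("%s%02d", ifelse(.data$group == "Ctrl", "C", "S"),
                                .data$pair_id),
           sex = c("F", rep("M", max(0, n_pairs - 1)))[.data$pair_id],
           age = round(truncnorm1(n(), 47, 14, 22, 75), 1),
           race = sample(c("White", "Black"), n(), TRUE, c(0.85, 0.15)),
           pmi_hr = round(truncnorm1(n(), 19, 8, 4, 45), 1),
           storage_months = round(truncnorm1(n(), 188, 20, 120, 260), 1),
           scale = lognormal_draw(n(), 1, params$subject_cv))

  cells <- tibble(type = c("vglut1", "vgat_high", "vgat_low"))
  grid <- tidyr::expand_grid(subjects, layer = layers, cells)
  cell_mean <- function(group, type) {
    nm <- c(vglut1 = "vglut1_cb1r_mean", vgat_high = "vgat_high_cb1r_mean",
            vgat_low = "vgat_low_cb1r_mean")[type]
    vapply(seq_along(group), function(i) params[[nm[i]]][[group[i]]], 0)
  }
  mu <- cell_mean(grid$group, grid$type) * grid$scale
  site_cv <- params$intensity_cv / sqrt(n_boutons_per_site[grid$type])
  vals <- vapply(seq_len(nrow(grid)), function(i) {
    mean(lognormal_draw(sites_per_layer, mu[i], site_cv[i]))
  }, 0)
  grid |> mutate(value = vals) |> select(-"scale")
}
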