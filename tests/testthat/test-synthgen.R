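test_that("empty scenes and invalid geometries behave as specified", {
  g <- small_geom(nx = 32, ny = 32, nz = 8)
  s <- generate_stack(g, clean_params(), seed = 1)
  expect_equal(max(abs(s$stack)), 0)
  expect_equal(nrow(s$truth), 0)

  expect_error(stack_geometry(nx = 0), class = "boutonquant_geometry_error")
  expect_error(stack_geometry(z_step = -1), class = "boutonquant_geometry_error")
  expect_error(stack_geometry(measured_thickness = 45),
               class = "boutonquant_geometry_error")
  expect_error(sim_params(high_fraction = 1.5),
               class = "boutonquant_param_error")
  expect_error(generate_cohort(sim_params(n_pairs = 1), g, layers = character()),
               class = "boutonquant_param_error")
})

test_that("a rendered marker matches its closed-form Gaussian integral and
           the receptor plateau matches the recorded truth", {
  g <- small_geom()
  p <- clean_params()
  tr <- truth_object("vglut1", 3.4, 3.4, 8.2, sigma_xy_um = 0.25,
                     marker_amp = 3000, cb1r_value = 800)
  st <- render_truth(tr, g, p)

  analytic <- 3000 * (2 * pi)^1.5 * 0.25^2 * 0.5 / voxel_volume(g)
  expect_lt(abs(sum(st[, , , "vglut1"]) / analytic - 1), 0.02)

  m <- truth_mask(tr, g)
  expect_equal(mean(st[, , , "cb1r"][m]), 800)

  # with attenuation on, the perfect-mask mean tracks the recorded truth
  p2 <- clean_params(depth_attenuation_rate = 0.02)
  s2 <- generate_stack(small_geom(), sim_params(
    densities_per_type = c(vglut1 = 10, vgat = 0, cb1r_only = 0),
    lipofuscin_density = 0, noise = list(gaussian_sd = 0, poisson_scale = 0),
    depth_attenuation_rate = 0.02), seed = 5, noise = FALSE)
  tr2 <- s2$truth[s2$truth$channel_role == "vglut1", ]
  for (i in seq_len(min(4, nrow(tr2)))) {
    mm <- truth_mask(tr2[i, ], small_geom())
    expect_lt(abs(mean(s2$stack[, , , "cb1r"][mm]) /
                    tr2$cb1r_mean_truth[i] - 1), 0.01)
  }
})

test_that("seeded generation is bit-reproducible and truth matches the scene", {
  g <- small_geom(nx = 48, ny = 48, nz = 12)
  p <- sim_params()
  a <- generate_stack(g, p, seed = 11)
  b <- generate_stack(g, p, seed = 11)
  expect_identical(a$stack, b$stack)
  expect_identical(a$truth, b$truth)

  # every truth object leaves signal in its primary channel
  ch_of <- c(vglut1 = "vglut1", vgat = "vgat", cb1r_only = "cb1r",
             lipofuscin = "lipofuscin")
  s <- generate_stack(g, p, seed = 12, noise = FALSE)
  for (i in seq_len(nrow(s$truth))) {
    o <- s$truth[i, ]
    m <- truth_mask(o, g, radius = 1)
    if (!any(m)) next  # center may fall outside the acquired band
    expect_gt(max(s$stack[, , , ch_of[[o$channel_role]]][m]), 0)
  }
})

test_that("doubling densities doubles expected object counts", {
  g <- small_geom(nx = 48, ny = 48, nz = 12)
  base <- sim_params()
  dbl <- sim_params(densities_per_type = 2 * base$densities_per_type,
                    lipofuscin_density = 2 * base$lipofuscin_density)
  n1 <- n2 <- 0
  for (s in 1:20) {
    n1 <- n1 + nrow(generate_stack(g, base, seed = s)$truth)
    n2 <- n2 + nrow(generate_stack(g, dbl, seed = 1000 + s)$truth)
  }
  expect_gt(n2 / n1, 1.8)
  expect_lt(n2 / n1, 2.2)
})

test_that("cohort manifests have the matched-pair shape", {
  co <- generate_cohort(sim_params(n_pairs = 10), small_geom(),
                        layers = layer_scheme()$layer, sites_per_layer = 6,
                        seed = 3)
  m <- co$manifest
  expect_equal(nrow(m), 10 * 2 * 6 * 6)  # pairs x groups x layers x sites
  expect_equal(dplyr::n_distinct(m$subject_id), 20)
  expect_setequal(unique(m$group), c("Ctrl", "SZ"))

  # pair members share sex and are close in age
  subj <- dplyr::distinct(m, subject_id, pair_id, group, sex, age)
  by_pair <- split(subj, subj$pair_id)
  for (pp in by_pair) {
    expect_equal(length(unique(pp$sex)), 1)
    expect_lt(abs(diff(pp$age)), 15)
  }
  # per-site seeds reproduce sites independently
  s1 <- generate_site(co, 1)
  s1b <- generate_site(co, m$site_id[1])
  expect_identical(s1$stack, s1b$stack)
})

test_that("layer scheme partitions the cortical depth", {
  ls <- layer_scheme()
  expect_equal(ls$lower[1], 0)
  expect_equal(ls$upper[nrow(ls)], 1)
  expect_equal(ls$lower[-1], ls$upper[-nrow(ls)])
})

test_that("table-level simulator is centered on its generating cell means", {
  p <- sim_params(n_pairs = 10)
  tab <- sim_measurement_table(p, layers = c("III", "V"), seed = 4)
  expect_equal(nrow(tab), 20 * 2 * 3)
  agg <- tab |>
    dplyr::group_by(group, type) |>
    dplyr::summarise(m = mean(value), .groups = "drop")
  ref <- reference_group_means()
  j <- dplyr::left_join(agg, ref, by = c("group", "type"))
  expect_true(all(abs(j$m / j$mean_adu - 1) < 0.1))
})
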