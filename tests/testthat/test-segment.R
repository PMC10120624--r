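test_that("voxel volume and the size gate follow the acquisition geometry", {
  g <- stack_geometry()
  v <- voxel_volume(g)
  expect_equal(v, (55 / 512)^2 * 0.25)
  expect_equal(ceiling(0.03 / v), 11)
  expect_equal(floor(2.0 / v), 693)

  expect_equal(voxel_volume(stack_geometry(pixel_size_xy = 1, z_step = 1,
                                           measured_thickness = 28)), 1)
  g2 <- stack_geometry(pixel_size_xy = 2 * 55 / 512)
  expect_equal(voxel_volume(g2), 4 * v)
})

test_that("Otsu threshold equals the brute-force between-class search", {
  x <- c(rep(0, 100), rep(1000, 100))
  t2 <- initial_threshold(x)
  expect_gt(t2, 0)
  expect_lte(t2, 1000)

  set.seed(42)
  for (i in 1:6) {
    img <- c(rpois(400, 30), rpois(60 + 20 * i, 300 + 50 * i))
    expect_equal(initial_threshold(img), otsu_brute(img), ignore_attr = TRUE)
  }

  # shift equivariance
  img <- c(rpois(300, 20), rpois(80, 200))
  expect_equal(initial_threshold(img + 57), initial_threshold(img) + 57)

  expect_error(initial_threshold(rep(7, 100)),
               class = "boutonquant_degenerate_error")
})

test_that("3-D labeling respects connectivity", {
  m <- array(FALSE, c(4, 4, 2))
  m[1, 1, 1] <- TRUE
  m[2, 2, 1] <- TRUE   # diagonal in XY
  m[4, 4, 2] <- TRUE
  l26 <- label_components(m, 26)
  l6 <- label_components(m, 6)
  expect_equal(max(l26), 2)  # diagonal pair joined
  expect_equal(max(l6), 3)   # all separate
  expect_equal(sum(l26 > 0), 3)
})

test_that("segmentation finds isolated puncta and measures them on the
           intensity channel", {
  g <- small_geom()
  p <- clean_params()

  zero <- array(0, c(g$nx, g$ny, g$nz))
  seg0 <- segment_channel(zero, zero, geometry = g)
  expect_equal(nrow(seg0$objects), 0)

  one <- truth_object("vglut1", 3.4, 3.4, 8.2, sigma_xy_um = 0.2,
                      marker_amp = 3000, cb1r_value = 800)
  st <- render_truth(one, g, p)
  enh <- difference_of_gaussians(st[, , , "vglut1"])
  seg <- segment_channel(enh, st[, , , "vglut1"], geometry = g,
                         channel = "vglut1")
  expect_equal(nrow(seg$objects), 1)
  expect_equal(seg$objects$x_um, 3.4, tolerance = 0.05)
  # receptor plateau under the segmented mask is recovered within 5%
  pos_mean <- mean(st[, , , "cb1r"][seg$labels == 1])
  expect_lt(abs(pos_mean / 800 - 1), 0.05)

  # merge/split limiting cases
  two <- dplyr::bind_rows(
    truth_object("vglut1", 2.4, 3.4, 8.2, sigma_xy_um = 0.2),
    truth_object("vglut1", 4.4, 3.4, 8.2, sigma_xy_um = 0.2))
  st2 <- render_truth(two, g, p)
  seg2 <- segment_channel(difference_of_gaussians(st2[, , , "vglut1"]),
                          st2[, , , "vglut1"], geometry = g)
  expect_equal(nrow(seg2$objects), 2)

  co <- dplyr::bind_rows(
    truth_object("vglut1", 3.4, 3.4, 8.2, sigma_xy_um = 0.2),
    truth_object("vglut1", 3.4, 3.4, 8.2, sigma_xy_um = 0.2))
  st3 <- render_truth(co, g, p)
  seg3 <- segment_channel(difference_of_gaussians(st3[, , , "vglut1"]),
                          st3[, , , "vglut1"], geometry = g)
  expect_equal(nrow(seg3$objects), 1)

  expect_error(segment_channel(enh, zero[1:10, , ], geometry = g),
               class = "boutonquant_input_error")
})

test_that("every final object volume lies inside the size gate", {
  g <- small_geom()
  s <- generate_stack(g, sim_params(), seed = 31)
  enh <- difference_of_gaussians(s$stack[, , , "vgat"])
  seg <- segment_channel(enh, s$stack[, , , "vgat"], geometry = g)
  expect_gt(nrow(seg$objects), 0)
  expect_true(all(seg$objects$volume_um3 >= 0.03))
  expect_true(all(seg$objects$volume_um3 <= 2.0))
  # labels and object table agree
  expect_equal(sort(unique(seg$labels[seg$labels > 0])),
               seg$objects$object_id)
  expect_equal(tabulate(seg$labels[seg$labels > 0]), seg$objects$n_voxels)
})

test_that("lipofuscin segmentation keeps oversized aggregates and an empty
           channel yields an empty exclusion mask", {
  g <- small_geom()
  p <- clean_params()

  lip0 <- segment_lipofuscin(array(0, c(g$nx, g$ny, g$nz)), geometry = g)
  expect_equal(sum(lip0$mask), 0)

  # one aggregate well above the 2 um^3 bouton gate
  blob <- truth_object("lipofuscin", 3.4, 3.4, 8.2, sigma_xy_um = 0.55,
                       lipofuscin_amp = 2000)
  st <- render_truth(blob, g, p)
  enh <- difference_of_gaussians(st[, , , "lipofuscin"])
  bouton_view <- segment_channel(enh, st[, , , "lipofuscin"], geometry = g)
  lip <- segment_lipofuscin(enh, geometry = g)
  # with the bouton gate only sub-2 um^3 core fragments survive, while the
  # ungated exclusion mask keeps the whole aggregate
  expect_true(all(bouton_view$objects$volume_um3 <= 2))
  expect_gt(sum(lip$mask) * voxel_volume(g), 2)
  expect_gt(sum(lip$mask), sum(bouton_view$labels > 0))
})

test_that("a noisy pure-background channel produces no exclusion mask", {
  g <- small_geom()
  set.seed(8)
  noise <- array(pmax(rnorm(g$nx * g$ny * g$nz, 0, 15), 0),
                 c(g$nx, g$ny, g$nz))
  enh <- difference_of_gaussians(noise)
  lip <- segment_lipofuscin(enh, geometry = g)
  expect_lt(sum(lip$mask) / length(lip$mask), 0.001)
})
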