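test_that("the marker-overlap exclusion rule matches its truth table", {
  fx <- overlap_fixture()
  masks <- list(vglut1 = fx$vglut1$labels > 0L, vgat = fx$vgat$labels > 0L)
  cb <- apply_filters(fx$cb1r, NULL, masks, default_frame(fx$g), fx$g)
  obj <- dplyr::arrange(cb$objects, x_um)
  expect_equal(nrow(obj), 4)
  # none / vglut1-only / vgat-only accepted; dual-marker rejected
  expect_equal(obj$accepted, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(obj$overlaps_vglut1, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(obj$overlaps_vgat, c(FALSE, FALSE, TRUE, TRUE))

  # marker objects: own channel counts as overlap, so only the dual pair
  # at (8, 8) is rejected
  vg <- apply_filters(fx$vglut1, NULL, masks, default_frame(fx$g), fx$g)
  vt <- apply_filters(fx$vgat, NULL, masks, default_frame(fx$g), fx$g)
  expect_equal(sum(vg$objects$accepted), 1)
  expect_equal(sum(vt$objects$accepted), 1)
})

test_that("lipofuscin overlap, depth window and counting frame each reject
           exactly the objects they should", {
  g <- small_geom(nx = 96, ny = 96, nz = 18)
  p <- clean_params()
  truth <- dplyr::bind_rows(
    truth_object("vglut1", 3.0, 3.0, 8.4, 0.2),   # clean, mid-window
    truth_object("vglut1", 6.0, 6.0, 8.4, 0.2),   # under lipofuscin
    truth_object("vglut1", 3.0, 6.0, 6.5, 0.2),   # corrected 9.3 um: shallow
    truth_object("vglut1", 0.5, 3.0, 8.4, 0.2),   # outside counting frame
    truth_object("lipofuscin", 6.0, 6.0, 8.4, 0.4, lipofuscin_amp = 2000))
  st <- render_truth(truth, g, p)
  vg <- segment_channel(difference_of_gaussians(st[, , , "vglut1"]),
                        st[, , , "vglut1"], geometry = g, channel = "vglut1")
  lip <- segment_lipofuscin(difference_of_gaussians(st[, , , "lipofuscin"]),
                            geometry = g)
  # a guard frame of 10 px (~1.07 um) on this 96-px field
  f <- apply_filters(vg, lip$mask, list(vglut1 = NULL, vgat = NULL),
                     filter_params(10, 14, frame_low = 10, frame_high = 86), g)
  obj <- dplyr::arrange(f$objects, y_um, x_um)
  expect_equal(nrow(obj), 4)
  acc <- f$objects$accepted
  expect_equal(sum(acc), 1)
  kept <- f$objects[acc, ]
  expect_equal(kept$x_um, 3.0, tolerance = 0.05)
  expect_equal(kept$y_um, 3.0, tolerance = 0.05)
  att <- attr(f$objects, "attrition")
  expect_equal(att$n_depth_reject, 1)
  expect_equal(att$n_frame_reject, 1)
  expect_equal(att$n_lipofuscin_reject, 1)

  # filters commute: flags are computed independently, so re-application
  # with the same masks is idempotent
  f2 <- apply_filters(f, lip$mask, list(vglut1 = NULL, vgat = NULL),
                      filter_params(10, 14, frame_low = 10, frame_high = 86), g)
  expect_equal(f2$objects$accepted, f$objects$accepted)
})

test_that("terminal typing measures CB1R under marker masks with metadata", {
  fx <- overlap_fixture()
  masks <- list(vglut1 = fx$vglut1$labels > 0L, vgat = fx$vgat$labels > 0L)
  vg <- apply_filters(fx$vglut1, NULL, masks, default_frame(fx$g), fx$g)
  vt <- apply_filters(fx$vgat, NULL, masks, default_frame(fx$g), fx$g)
  info <- tibble::tibble(subject_id = "C01", pair_id = 1, group = "Ctrl",
                         layer = "III", site_id = "s1")
  rec <- classify_terminal_type(vg, vt, fx$st[, , , "cb1r"], info)
  expect_equal(nrow(rec), 2)
  expect_setequal(rec$terminal_type, c("vglut1", "vgat"))
  # accepted markers sit on 900-ADU CB1R puncta plus their own 700 plateau
  expect_true(all(rec$cb1r_mean > 700))
  expect_equal(rec$subject_id, rep("C01", 2))

  # constant CB1R field: mean equals the constant
  flat <- array(512, dim(fx$st)[1:3])
  rec2 <- classify_terminal_type(vg, vt, flat, info)
  expect_equal(rec2$cb1r_mean, rep(512, 2))

  zero <- array(0, dim(fx$st)[1:3])
  rec3 <- classify_terminal_type(vg, vt, zero, info)
  expect_equal(rec3$cb1r_mean, rep(0, 2))

  expect_error(classify_terminal_type(vg, vt, flat, list(group = "Ctrl")),
               class = "boutonquant_input_error")
})

test_that("the expressor split partitions vGAT records at the control
           median", {
  r <- tibble::tibble(group = "Ctrl", terminal_type = "vgat",
                      cb1r_mean = c(400, 700, 2500))
  s <- split_expressor_class(r)
  expect_equal(attr(s, "split_adu"), 700)
  expect_equal(s$expressor_class, c("low", "low", "high"))  # tie -> low

  mixed <- tibble::tibble(
    group = rep(c("Ctrl", "SZ"), each = 4),
    terminal_type = rep(c("vgat", "vgat", "vgat", "vglut1"), 2),
    subject_id = rep(c("C1", "S1"), each = 4),
    cb1r_mean = c(300, 500, 2600, 800, 350, 2400, 2800, 900))
  m <- split_expressor_class(mixed)
  expect_true(all(is.na(m$expressor_class[m$terminal_type == "vglut1"])))
  vgat <- m[m$terminal_type == "vgat", ]
  expect_equal(sum(vgat$expressor_class == "high") +
                 sum(vgat$expressor_class == "low"), nrow(vgat))

  expect_error(split_expressor_class(
    tibble::tibble(group = "SZ", terminal_type = "vgat", cb1r_mean = 1)),
    class = "boutonquant_input_error")
})

test_that("the split recovers mixture proportions across seeds", {
  hits <- replicate(20, {
    set.seed(sample.int(1e6, 1))
    n <- 400
    hi <- runif(n) < 0.5
    vals <- ifelse(hi, rlnorm(n, log(2510), 0.1), rlnorm(n, log(435), 0.1))
    rec <- tibble::tibble(group = "Ctrl", terminal_type = "vgat",
                          cb1r_mean = vals)
    s <- split_expressor_class(rec)
    mean(s$expressor_class == "high")
  })
  expect_lt(abs(mean(hits) - 0.5), 0.03)
})

test_that("site summaries average per type and sum CB1R on the selected
           plane", {
  rec <- tibble::tibble(subject_id = "C01", pair_id = 1, group = "Ctrl",
                        layer = "III", site_id = "s1",
                        terminal_type = c("vglut1", "vglut1", "vgat", "vgat"),
                        cb1r_mean = c(400, 600, 2600, 300),
                        expressor_class = c(NA, NA, "high", "low"))
  ss <- summarize_site(rec)
  expect_equal(ss$mean_cb1r_vglut1, 500)
  expect_equal(ss$mean_cb1r_vgat_high, 2600)
  expect_equal(ss$mean_cb1r_vgat_low, 300)
  expect_equal(ss$n_vglut1, 2)
  expect_true(is.na(ss$sum_cb1r))

  # empty site: means undefined, not zero
  ss0 <- summarize_site(rec[0, ], info = list(subject_id = "C01",
                                              site_id = "s1"))
  expect_true(is.na(ss0$mean_cb1r_vglut1))
  expect_equal(ss0$n_vglut1, 0)

  # brute-force voxel-sum oracle for the single-plane sum measure
  fx <- overlap_fixture()
  masks <- list(vglut1 = fx$vglut1$labels > 0L, vgat = fx$vgat$labels > 0L)
  cb <- apply_filters(fx$cb1r, NULL, masks, default_frame(fx$g), fx$g)
  ss2 <- summarize_site(rec, cb1r_seg = cb, cb1r_channel = fx$st[, , , "cb1r"],
                        geometry = fx$g, filters = default_frame(fx$g))
  plane <- ss2$sum_plane
  acc <- cb$objects$object_id[cb$objects$accepted]
  oracle <- 0
  for (ix in seq_len(fx$g$nx)) for (iy in seq_len(fx$g$ny)) {
    if (cb$labels[ix, iy, plane] %in% acc) {
      oracle <- oracle + fx$st[ix, iy, plane, "cb1r"]
    }
  }
  expect_equal(ss2$sum_cb1r, as.numeric(oracle))
  expect_gt(ss2$sum_cb1r, 0)
})

test_that("layer aggregation is the unweighted subject-by-layer mean", {
  ss <- tibble::tibble(subject_id = "C01", pair_id = 1, group = "Ctrl",
                       layer = "III", site_id = c("s1", "s2", "s3"),
                       mean_cb1r_vglut1 = c(10, 20, 30),
                       mean_cb1r_vgat_high = c(5, NA, 15),
                       mean_cb1r_vgat_low = NA_real_,
                       sum_cb1r = c(100, 200, 300))
  la <- summarize_layer(ss)
  expect_equal(nrow(la), 1)
  expect_equal(la$mean_cb1r_vglut1, 20)
  expect_equal(la$mean_cb1r_vgat_high, 10)  # NA site dropped, not zeroed
  expect_true(is.na(la$mean_cb1r_vgat_low))
  expect_equal(la$sum_cb1r, 200)
  expect_equal(la$n_sites, 3)

  # random table equals an independent group-by-mean oracle
  set.seed(5)
  big <- tidyr::expand_grid(subject_id = paste0("S", 1:6),
                            layer = c("I", "III"), site_id = 1:4) |>
    dplyr::mutate(pair_id = 1, group = "SZ",
                  mean_cb1r_vglut1 = runif(dplyr::n(), 100, 1000),
                  mean_cb1r_vgat_high = runif(dplyr::n(), 100, 1000),
                  mean_cb1r_vgat_low = runif(dplyr::n(), 100, 1000),
                  sum_cb1r = runif(dplyr::n()))
  la2 <- summarize_layer(big)
  oracle <- tapply(big$mean_cb1r_vglut1,
                   interaction(big$subject_id, big$layer), mean)
  got <- setNames(la2$mean_cb1r_vglut1,
                  paste(la2$subject_id, la2$layer, sep = "."))
  expect_equal(got[names(oracle)], oracle[names(oracle)],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(nrow(layer_type_table(la2)), 6 * 2 * 3)
})
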