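test_that("a one-factor balanced ANCOVA reproduces the pooled t squared", {
  set.seed(14)
  for (i in 1:4) {
    d <- tibble::tibble(group = rep(c("Ctrl", "SZ"), each = 12),
                        value = rnorm(24, mean = rep(c(0, i), each = 12)))
    fit <- fit_ancova(d, model_spec("value", "group"))
    t_or <- pooled_t_brute(d$value[d$group == "Ctrl"],
                           d$value[d$group == "SZ"])
    expect_equal(tidy(fit)$F, t_or^2, tolerance = 1e-8)
    expect_equal(tidy(fit)$df_den, 22)
  }
})

test_that("degenerate and rank-deficient designs are flagged", {
  d <- tibble::tibble(group = rep(c("a", "b"), 6), value = 5)
  expect_warning(fit <- fit_ancova(d, model_spec("value", "group")),
                 "constant")
  expect_equal(tidy(fit)$F, 0)

  d2 <- tibble::tibble(group = rep(c("a", "b"), each = 6),
                       twin = rep(c("x", "y"), each = 6),  # aliased with group
                       value = rnorm(12))
  expect_error(fit_ancova(d2, model_spec("value", c("group", "twin"))),
               class = "boutonquant_model_error")

  expect_error(model_spec("y", "group", blocking = "pair",
                          covariates = "age"),
               class = "boutonquant_param_error")
})

test_that("Type III F statistics are invariant to factor level order", {
  d <- sim_measurement_table(sim_params(n_pairs = 6), layers = "III",
                             seed = 8)
  spec <- model_spec("value", c("group", "type", "group:type"),
                     blocking = "pair_id")
  f1 <- tidy(fit_ancova(d, spec))
  d2 <- d
  d2$type <- factor(d2$type, levels = c("vgat_low", "vglut1", "vgat_high"))
  d2$group <- factor(d2$group, levels = c("SZ", "Ctrl"))
  f2 <- tidy(fit_ancova(d2, spec))
  expect_equal(f1$F, f2$F, tolerance = 1e-8)
})

test_that("paired and unpaired models agree on the direction and rough size
           of the group effect", {
  d <- sim_measurement_table(sim_params(n_pairs = 10), layers = "III",
                             seed = 15)
  d <- d[d$type == "vglut1", ]
  paired <- fit_ancova(d, model_spec("value", "group", blocking = "pair_id"))
  unpaired <- fit_ancova(d, model_spec("value", "group",
                                       covariates = c("sex", "race", "age",
                                                      "pmi_hr",
                                                      "storage_months")))
  fp <- tidy(paired); fu <- tidy(unpaired)
  expect_lt(fp$p[fp$term == "group"], 0.05)
  expect_lt(fu$p[fu$term == "group"], 0.05)
  cp <- coef(paired$fit)[["group1"]]
  cu <- coef(unpaired$fit)[["group1"]]
  expect_equal(sign(cp), sign(cu))
  expect_lt(abs(cp / cu - 1), 0.5)
})

test_that("Bonferroni adjustment multiplies, caps and never shrinks", {
  expect_equal(bonferroni_adjust(0.02, 3), 0.06)
  expect_equal(bonferroni_adjust(0.6, 3), 1)
  expect_error(bonferroni_adjust(0.5, 0), class = "boutonquant_param_error")

  d <- sim_measurement_table(sim_params(n_pairs = 8), layers = "III",
                             seed = 21)
  fit <- fit_ancova(d, model_spec("value", c("group", "type", "group:type"),
                                  blocking = "pair_id"))
  ph <- posthoc_bonferroni(fit)
  expect_true(all(ph$adjusted_p >= ph$p - 1e-12))
  expect_true(all(ph$adjusted_p <= 1))
  expect_equal(nrow(ph), 3)  # one group contrast per terminal type
})

test_that("percent group differences reproduce the reference arithmetic", {
  ref <- reference_group_means()
  wide <- tidyr::pivot_wider(ref[, c("type", "group", "mean_adu")],
                             names_from = "group", values_from = "mean_adu")
  pd <- group_percent_difference(wide$SZ, wide$Ctrl)
  names(pd) <- wide$type
  expect_equal(round(pd[["vglut1"]], 1), 35.3)
  expect_equal(round(pd[["vgat_high"]], 1), -14.9)
  expect_equal(group_percent_difference(500, 500), 0)
  expect_error(group_percent_difference(1, 0),
               class = "boutonquant_param_error")
})

test_that("the within-pair ratio t test matches the textbook pooled
           formula", {
  same <- c(0.9, 1.0, 1.1, 1.2)
  res <- within_pair_ratio_test(c(same, same),
                                rep(c(TRUE, FALSE), each = 4))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  set.seed(3)
  r <- runif(10, 0.5, 1.5)
  e <- rep(c(TRUE, FALSE), c(3, 7))
  res2 <- within_pair_ratio_test(r, e)
  expect_equal(res2$t, pooled_t_brute(r[e], r[!e]), tolerance = 1e-12)
  expect_equal(res2$df, 8)

  expect_error(within_pair_ratio_test(r, rep(TRUE, 10)),
               class = "boutonquant_input_error")
  expect_warning(within_pair_ratio_test(r, rep(c(TRUE, FALSE), c(1, 9))),
                 "n = 1")
})

test_that("the reciprocal-ratio table reproduces the published arithmetic", {
  ref <- reference_pair_ratios()
  tab <- build_pair_ratio_table(ref$ihc_ratio_pct, ref$ligand_ratio_pct,
                                ref$pair_id)
  expect_equal(tab$magnitude_difference,
               tab$ligand_ratio_pct - tab$ihc_ratio_pct)
  expect_equal(round(tab$magnitude_difference[1], 2), 31.33)
  expect_equal(round(tab$magnitude_difference[4], 2), 106.46)
  gl <- glance(tab)
  expect_equal(round(gl$ihc_mean, 2), -18.83)
  # exact SD is 9.20486; the published 9.21 is the half-up rounding of 9.205
  expect_lt(abs(gl$ihc_sd - 9.21), 0.0052)
  expect_equal(round(gl$magnitude_mean, 2), 46.12)
  expect_equal(round(gl$magnitude_sd, 2), 27.84)

  expect_error(build_pair_ratio_table(1:3, 1:4),
               class = "boutonquant_input_error")
})

test_that("demographic tests use Fisher for categories and pooled t for
           continuous variables", {
  subj <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:20),
    group = rep(c("Ctrl", "SZ"), each = 10),
    cannabis_use = rep(c(FALSE, TRUE), c(17, 3)),  # 0/10 vs 3/10
    age = c(rnorm(10, 47, 5), rnorm(10, 48, 5)))
  out <- demographic_tests(subj)
  p_cannabis <- out$p[out$variable == "cannabis_use"]
  expect_equal(round(p_cannabis, 2), 0.21)
  expect_equal(p_cannabis, fisher_brute(0, 10, 3, 7), tolerance = 1e-9)
  expect_equal(out$test[out$variable == "age"], "t")

  same <- subj
  same$age <- rep(c(rnorm(10, 50, 4)), 2)
  expect_equal(demographic_tests(same)$p[2], 1, tolerance = 1e-9)

  # random 2x2 tables: fisher.test equals the enumeration oracle
  set.seed(77)
  for (i in 1:5) {
    a <- sample(0:6, 1); b <- 8 - a; c <- sample(0:6, 1); d <- 8 - c
    x <- rep(c("u", "v", "u", "v"), c(a, b, c, d))
    grp <- rep(c("Ctrl", "SZ"), each = 8)
    got <- demographic_tests(tibble::tibble(group = grp, var = x),
                             variables = "var")$p
    expect_equal(got, fisher_brute(a, b, c, d), tolerance = 1e-9)
  }
})
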