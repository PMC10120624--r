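# End-to-end pipeline: (synthetic) stacks -> enhancement -> segmentation
# -> filtering -> terminal typing -> site/layer aggregation -> statistics.

#' Assemble a pipeline configuration
#'
#' @param sim A [sim_params()] (the synthetic cohort to generate), or a
#'   directory containing `manifest.csv` and site TIFFs from
#'   [write_cohort()].
#' @param geometry A [stack_geometry()].
#' @param enhancement An [enhancement_params()].
#' @param segmentation A [segmentation_params()].
#' @param filters A [filter_params()] or `NULL` to derive the 2% counting
#'   frame from the geometry.
#' @param layers Layer labels to sample.
#' @param sites_per_layer Sites per layer per subject.
#' @param seed Master seed, recorded in all outputs.
#' @param noise Simulate noise when generating stacks.
#' @param measure_sum Also segment the CB1R channel and measure single-plane
#'   sum intensity (slower; required for the sum-CB1R models).
#' @param expressor_level Level at which the control median defining
#'   high/low inhibitory expressor classes is computed: `"subject"`
#'   (median of control subject means; robust when the within-subject
#'   distribution is strongly bimodal — see vignette) or `"bouton"`
#'   (pooled control boutons).
#' @param out_dir Optional directory for stamped CSV outputs.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_params(), geometry = stack_geometry(),
                            enhancement = enhancement_params(),
                            segmentation = segmentation_params(),
                            filters = NULL, layers = layer_scheme()$layer,
                            sites_per_layer = 6, seed = 1, noise = TRUE,
                            measure_sum = TRUE,
                            expressor_level = c("subject", "bouton"),
                            out_dir = NULL) {
  structure(list(sim = sim, geometry = geometry, enhancement = enhancement,
                 segmentation = segmentation, filters = filters,
                 layers = layers, sites_per_layer = sites_per_layer,
                 seed = seed, noise = noise, measure_sum = measure_sum,
                 expressor_level = match.arg(expressor_level),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `sim`, `geometry`, `enhancement`, `segmentation`,
#' `filters` are passed as argument lists to the corresponding parameter
#' constructors; remaining keys map to [pipeline_config()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(key, ctor) {
    if (is.null(y[[key]])) return(ctor())
    args <- y[[key]]
    for (nm in names(args)) if (is.list(args[[nm]]) &&
                                all(vapply(args[[nm]], is.numeric, TRUE)) &&
                                !is.null(names(args[[nm]]))) {
      args[[nm]] <- unlist(args[[nm]])
    }
    do.call(ctor, args)
  }
  pipeline_config(
    sim = build("sim", sim_params),
    geometry = build("geometry", stack_geometry),
    enhancement = build("enhancement", enhancement_params),
    segmentation = build("segmentation", segmentation_params),
    filters = if (is.null(y$filters)) NULL else do.call(filter_params, y$filters),
    layers = y$layers %||% layer_scheme()$layer,
    sites_per_layer = y$sites_per_layer %||% 6,
    seed = y$seed %||% 1,
    noise = y$noise %||% TRUE,
    measure_sum = y$measure_sum %||% TRUE,
    expressor_level = y$expressor_level %||% "subject",
    out_dir = y$out_dir)
}

#' Validate a pipeline configuration
#'
#' Re-runs every parameter-type invariant and returns all violations, not
#' just the first.
#'
#' @param config A `pipeline_config` (or a YAML path).
#' @return Character vector of violations; `character(0)` means the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  probs <- character()
  try_check <- function(expr) {
    tryCatch({ force(expr); NULL }, error = function(e) conditionMessage(e))
  }
  add <- function(msg) if (!is.null(msg)) probs <<- c(probs, msg)
  add(try_check(validate_geometry(config$geometry)))
  add(try_check(validate_sim_params(config$sim)))
  add(try_check(do.call(enhancement_params,
                        config$enhancement[c("sigma_narrow", "sigma_wide")])))
  add(try_check(do.call(segmentation_params,
                        unclass(config$segmentation))))
  if (!is.null(config$filters)) {
    add(try_check(do.call(filter_params, unclass(config$filters))))
  }
  if (length(config$layers) == 0) probs <- c(probs, "layers must be nonempty")
  if (!isTRUE(config$sites_per_layer >= 1)) {
    probs <- c(probs, "sites_per_layer must be >= 1")
  }
  probs
}

#' Process one stack through enhancement, segmentation and typing
#'
#' Exposure-normalizes the stack, DoG-enhances every channel, segments the
#' lipofuscin exclusion mask and the marker (and optionally CB1R)
#' channels, applies the acceptance filters, and returns the typed bouton
#' records and the site's single-plane sum-CB1R measure.
#'
#' @param stack 4-D array `[x, y, z, channel]` of raw ADU.
#' @param geometry The site's [stack_geometry()] (with actual exposures).
#' @param info Site metadata row (subject/pair/group/layer/site).
#' @param enhancement,segmentation,filters Parameter objects.
#' @param reference_exposure Named per-channel reference exposures; the
#'   default is the nominal optimal exposure set.
#' @param measure_sum Also segment CB1R for the sum-intensity measure.
#' @return List: `records` (typed boutons, no expressor class yet),
#'   `sum_cb1r`, `attrition` (per-channel filter attrition), `segs`
#'   (the filtered segmentations).
#' @export
process_stack <- function(stack, geometry, info,
                          enhancement = enhancement_params(),
                          segmentation = segmentation_params(),
                          filters = default_frame(geometry),
                          reference_exposure = NULL,
                          measure_sum = TRUE) {
  ref <- reference_exposure %||% NOMINAL_EXPOSURE
  stk <- normalize_exposure(stack, geometry$exposure_times, ref)
  enh <- enhance_stack(stk, enhancement)

  lip <- segment_lipofuscin(enh[, , , "lipofuscin"], segmentation, geometry)
  seg_one <- function(ch) {
    segment_channel(enh[, , , ch], stk[, , , ch], segmentation, geometry,
                    channel = ch)
  }
  vglut1 <- seg_one("vglut1")
  vgat <- seg_one("vgat")
  masks <- list(vglut1 = vglut1$labels > 0L, vgat = vgat$labels > 0L)

  vglut1 <- apply_filters(vglut1, lip$mask, masks, filters, geometry)
  vgat <- apply_filters(vgat, lip$mask, masks, filters, geometry)
  records <- classify_terminal_type(vglut1, vgat, stk[, , , "cb1r"], info)

  sum_cb1r <- NA_real_
  cb1r <- NULL
  if (measure_sum) {
    cb1r <- apply_filters(seg_one("cb1r"), lip$mask, masks, filters, geometry)
    plane <- sum_plane_index(geometry, filters)
    acc <- cb1r$objects$object_id[cb1r$objects$accepted]
    sl <- cb1r$labels[, , plane]
    sum_cb1r <- sum(stk[, , plane, "cb1r"][sl %in% acc])
  }
  attrition <- bind_rows(attr(vglut1$objects, "attrition"),
                         attr(vgat$objects, "attrition"),
                         if (!is.null(cb1r)) attr(cb1r$objects, "attrition"))
  attrition$site_id <- info$site_id[[1]]
  list(records = records, sum_cb1r = sum_cb1r, attrition = attrition,
       segs = list(vglut1 = vglut1, vgat = vgat, cb1r = cb1r,
                   lipofuscin = lip$segmentation))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates the cohort manifest, processes every site
#' ([process_stack()]), splits inhibitory boutons at the control median,
#' aggregates to sites and layers, and fits the study's models: paired
#' (pair-blocked) and unpaired (covariate-adjusted) ANCOVAs for sum CB1R
#' and for terminal-type mean CB1R, Bonferroni post hocs on the group
#' contrasts within type, estimated group percent differences, and
#' within-pair ratio t tests against cannabis exposure. Layer terms are
#' included only when more than one layer is sampled.
#'
#' @param config A [pipeline_config()] (or YAML path).
#' @param keep_segs Keep per-site segmentations (memory-heavy; default
#'   drops them).
#' @return An object of class `cb1r_pipeline_result`: list with
#'   `manifest`, `records`, `site_summaries`, `layer_summaries`,
#'   `type_table`, `split_adu`, `fits`, `posthoc`, `percent_differences`,
#'   `exposure_tests`, `attrition`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), keep_segs = FALSE) {
  if (is.character(config)) config <- read_config(config)
  probs <- validate_config(config)
  if (length(probs)) {
    abort(c("invalid pipeline configuration", probs),
          class = "boutonquant_config_error")
  }
  cohort <- generate_cohort(config$sim, config$geometry, config$layers,
                            config$sites_per_layer, seed = config$seed,
                            noise = config$noise)
  m <- cohort$manifest
  filters <- config$filters
  rec_list <- vector("list", nrow(m))
  sum_list <- numeric(nrow(m))
  att_list <- vector("list", nrow(m))
  segs <- if (keep_segs) vector("list", nrow(m)) else NULL

  for (i in seq_len(nrow(m))) {
    site <- tryCatch(generate_site(cohort, i), error = function(e) {
      abort(sprintf("stage synthgen failed at site %s: %s", m$site_id[i],
                    conditionMessage(e)), class = "boutonquant_stage_error")
    })
    f <- filters %||% default_frame(site$geometry)
    res <- tryCatch(
      process_stack(site$stack, site$geometry, site$info,
                    config$enhancement, config$segmentation, f,
                    measure_sum = config$measure_sum),
      error = function(e) {
        abort(sprintf("stage imgproc/segment/measure failed at site %s: %s",
                      m$site_id[i], conditionMessage(e)),
              class = "boutonquant_stage_error")
      })
    rec_list[[i]] <- res$records
    sum_list[i] <- res$sum_cb1r
    att_list[[i]] <- res$attrition
    if (keep_segs) segs[[i]] <- res$segs
  }

  records <- bind_rows(rec_list)
  if (nrow(records)) {
    records <- split_expressor_class(records,
                                     level = config$expressor_level %||% "subject")
  }
  split_adu <- attr(records, "split_adu")

  site_rows <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    site_recs <- records[records$site_id == m$site_id[i], ]
    site_rows[[i]] <- summarize_site(site_recs, info = m[i, ],
                                     sum_cb1r = if (config$measure_sum) sum_list[i])
  }
  site_summaries <- bind_rows(site_rows)
  layer_summaries <- summarize_layer(site_summaries)
  type_table <- layer_type_table(layer_summaries) |>
    left_join(distinct(m[, c("subject_id", "sex", "race", "age", "pmi_hr",
                             "storage_months", "cannabis_use")]),
              by = "subject_id")

  multi_layer <- length(unique(m$layer)) > 1
  covars <- c("sex", "race", "age", "pmi_hr", "storage_months")
  sum_fixed <- if (multi_layer) c("group", "layer", "group:layer") else "group"
  type_fixed <- if (multi_layer) {
    c("group", "layer", "type", "group:type", "group:layer:type")
  } else {
    c("group", "type", "group:type")
  }
  sum_data <- layer_summaries |>
    left_join(distinct(m[, c("subject_id", covars)]), by = "subject_id")

  # sparse cohorts (few pairs, missing cells) can leave a model
  # inestimable; keep the rest of the result usable and say so
  try_fit <- function(data, spec) {
    tryCatch(fit_ancova(data, spec), error = function(e) {
      rlang::inform(paste("model skipped:", conditionMessage(e)))
      NULL
    })
  }
  fits <- list()
  if (config$measure_sum && any(!is.na(sum_data$sum_cb1r))) {
    fits$paired_sum <- try_fit(sum_data,
                               model_spec("sum_cb1r", sum_fixed, blocking = "pair_id"))
    fits$unpaired_sum <- try_fit(sum_data,
                                 model_spec("sum_cb1r", sum_fixed, covariates = covars))
  }
  if (nrow(type_table)) {
    fits$paired_type <- try_fit(type_table,
                                model_spec("value", type_fixed, blocking = "pair_id"))
    fits$unpaired_type <- try_fit(type_table,
                                  model_spec("value", type_fixed, covariates = covars))
  }
  posthoc <- if (!is.null(fits$paired_type)) posthoc_bonferroni(fits$paired_type)

  cell_means <- type_table |>
    group_by(.data$group, .data$type) |>
    summarise(mean = mean(.data$value), .groups = "drop")
  percent_differences <- cell_means |>
    tidyr::pivot_wider(names_from = "group", values_from = "mean") |>
    mutate(percent_difference = group_percent_difference(.data$SZ, .data$Ctrl))

  exposure_tests <- pipeline_exposure_tests(type_table, sum_data, m)

  out <- structure(list(manifest = m, records = records,
                        site_summaries = site_summaries,
                        layer_summaries = layer_summaries,
                        type_table = type_table, split_adu = split_adu,
                        fits = fits, posthoc = posthoc,
                        percent_differences = percent_differences,
                        exposure_tests = exposure_tests,
                        attrition = bind_rows(att_list),
                        segs = segs, config = config),
                   class = "cb1r_pipeline_result")
  if (!is.null(config$out_dir)) write_results(out, config$out_dir)
  out
}

# within-pair Ctrl/SZ ratios of subject-level means, tested against the
# SZ member's cannabis exposure
pipeline_exposure_tests <- function(type_table, sum_data, manifest) {
  flags <- manifest |>
    filter(.data$group == "SZ") |>
    distinct(.data$pair_id, .data$cannabis_use)
  if (nrow(flags) < 2 || length(unique(flags$cannabis_use)) < 2) return(NULL)

  subject_means <- type_table |>
    group_by(.data$pair_id, .data$group) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "value") |>
    mutate(ratio = .data$Ctrl / .data$SZ) |>
    left_join(flags, by = "pair_id")
  mean_test <- within_pair_ratio_test(subject_means$ratio,
                                      subject_means$cannabis_use) |>
    mutate(measure = "mean_cb1r", .before = 1)

  sum_test <- NULL
  if ("sum_cb1r" %in% names(sum_data) && any(!is.na(sum_data$sum_cb1r))) {
    s <- sum_data |>
      group_by(.data$pair_id, .data$group) |>
      summarise(value = mean(.data$sum_cb1r), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "group", values_from = "value") |>
      mutate(ratio = .data$Ctrl / .data$SZ) |>
      left_join(flags, by = "pair_id")
    sum_test <- within_pair_ratio_test(s$ratio, s$cannabis_use) |>
      mutate(measure = "sum_cb1r", .before = 1)
  }
  bind_rows(mean_test, sum_test)
}

#' Write pipeline result tables as stamped CSVs
#'
#' @param result A `cb1r_pipeline_result`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  w <- function(x, name) {
    if (!is.null(x) && nrow(x)) {
      write_stamped_csv(x, file.path(out_dir, name), config = cfg,
                        seed = cfg$seed)
    }
  }
  w(result$records, "bouton_records.csv")
  w(result$site_summaries, "site_summaries.csv")
  w(result$layer_summaries, "layer_summaries.csv")
  w(result$attrition, "attrition.csv")
  anova_tab <- purrr::imap(result$fits,
                           ~ mutate(tidy(.x), model = .y, .before = 1)) |>
    bind_rows()
  w(anova_tab, "anova_results.csv")
  w(result$percent_differences, "percent_differences.csv")
  invisible(out_dir)
}

#' @export
print.cb1r_pipeline_result <- function(x, ...) {
  cat(sprintf("<cb1r_pipeline_result> %d sites, %d boutons (split at %.1f ADU)\n",
              nrow(x$manifest), nrow(x$records), x$split_adu %||% NA))
  if (!is.null(x$percent_differences)) {
    pd <- x$percent_differences
    for (i in seq_len(nrow(pd))) {
      cat(sprintf("  %-10s SZ vs Ctrl: %+.1f%%\n", pd$type[i],
                  pd$percent_difference[i]))
    }
  }
  if (!is.null(x$fits$paired_type)) {
    a <- x$fits$paired_type$anova
    gt <- a[a$term == "group:type", ]
    if (nrow(gt)) cat(sprintf("  group x type interaction: F(%d,%d) = %.3f, p = %.3g\n",
                              gt$df_num, gt$df_den, gt$F, gt$p))
  }
  invisible(x)
}
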