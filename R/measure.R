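# Acceptance filtering, terminal typing, expressor splitting and
# site/layer aggregation of segmented objects.

#' Object acceptance filters
#'
#' Depth window and XY counting frame applied to segmented objects before
#' analysis. Defaults follow the acquisition convention: objects must lie
#' 10–14 um below the tissue surface after shrinkage correction (the zone
#' of uniform antibody penetrance), and their centroids must fall inside a
#' guard frame excluding the outer 2% of each XY dimension (pixels 10–502
#' on a 512-pixel frame).
#'
#' @param depth_min,depth_max Corrected depth window (um).
#' @param frame_low,frame_high Counting-frame bounds (pixels); `NULL`
#'   derives the 2% guard from a geometry via [default_frame()].
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(depth_min = 10, depth_max = 14,
                          frame_low = 10, frame_high = 502) {
  if (!isTRUE(depth_min < depth_max)) {
    abort("FilterParams: depth_min must be < depth_max",
          class = "boutonquant_param_error")
  }
  if (!isTRUE(frame_low < frame_high)) {
    abort("FilterParams: frame_low must be < frame_high",
          class = "boutonquant_param_error")
  }
  structure(list(depth_min = depth_min, depth_max = depth_max,
                 frame_low = frame_low, frame_high = frame_high),
            class = "filter_params")
}

#' 2% guard counting frame for a geometry
#'
#' @param geometry A [stack_geometry()].
#' @param depth_min,depth_max Corrected depth window (um).
#' @return A [filter_params()] whose frame excludes the outer 2% of the XY
#'   field (`round(0.02 * n)` to `round(0.98 * n)`; 10–502 at 512 pixels).
#' @export
default_frame <- function(geometry, depth_min = 10, depth_max = 14) {
  n <- min(geometry$nx, geometry$ny)
  filter_params(depth_min, depth_max,
                frame_low = round(0.02 * n), frame_high = round(0.98 * n))
}

# object ids of a segmentation whose masks share >= 1 voxel with `mask`
overlapping_ids <- function(seg, mask) {
  if (is.null(mask)) return(integer())
  lab <- seg$labels
  sort(unique(lab[mask & lab > 0L]))
}

#' Apply the acceptance filters to segmented objects
#'
#' An object is rejected if (a) its shrinkage-corrected centroid depth
#' falls outside the depth window, (b) its centroid falls outside the XY
#' counting frame, (c) any of its voxels overlaps the lipofuscin exclusion
#' mask, or (d) it overlaps *both* the vGlut1 and the vGAT bouton masks
#' (ambiguous dual-marker objects). A marker object counts as overlapping
#' its own channel's mask, so rule (d) reduces to "overlaps the other
#' marker" for vGlut1/vGAT objects. The filters commute; their order never
#' changes the result.
#'
#' @param seg A `bouton_segmentation` from [segment_channel()].
#' @param lipofuscin_mask Logical array from [segment_lipofuscin()], or
#'   `NULL`.
#' @param marker_masks Named list of logical arrays `vglut1` and `vgat`
#'   (either may be `NULL`).
#' @param filters A [filter_params()].
#' @param geometry The stack's [stack_geometry()].
#' @return The segmentation with its `objects` tibble gaining
#'   `depth_corrected_um`, `in_depth_window`, `in_frame`,
#'   `overlaps_lipofuscin`, `overlaps_vglut1`, `overlaps_vgat`, `accepted`;
#'   and an `attrition` tibble attribute counting rejections per rule.
#' @export
apply_filters <- function(seg, lipofuscin_mask = NULL,
                          marker_masks = list(vglut1 = NULL, vgat = NULL),
                          filters = default_frame(geometry),
                          geometry = seg$geometry) {
  for (m in c(list(lipofuscin_mask), unname(marker_masks))) {
    if (!is.null(m) && !identical(dim(m), dim(seg$labels))) {
      abort("mask geometry does not match the segmentation",
            class = "boutonquant_input_error")
    }
  }
  obj <- seg$objects
  px <- geometry$pixel_size_xy
  depth <- correct_z_shrinkage(obj$z_um, geometry$measured_thickness,
                               geometry$original_thickness)
  cx <- obj$x_um / px + 0.5   # centroid in pixel units (center of px i = i)
  cy <- obj$y_um / px + 0.5

  ov <- function(mask) obj$object_id %in% overlapping_ids(seg, mask)
  obj$depth_corrected_um <- depth
  obj$in_depth_window <- depth >= filters$depth_min & depth <= filters$depth_max
  obj$in_frame <- cx >= filters$frame_low & cx <= filters$frame_high &
    cy >= filters$frame_low & cy <= filters$frame_high
  obj$overlaps_lipofuscin <- ov(lipofuscin_mask)
  obj$overlaps_vglut1 <- if (seg$channel == "vglut1") TRUE else ov(marker_masks$vglut1)
  obj$overlaps_vgat <- if (seg$channel == "vgat") TRUE else ov(marker_masks$vgat)
  obj$accepted <- obj$in_depth_window & obj$in_frame &
    !obj$overlaps_lipofuscin & !(obj$overlaps_vglut1 & obj$overlaps_vgat)

  attr(obj, "attrition") <- tibble(
    channel = seg$channel,
    n_total = nrow(obj),
    n_depth_reject = sum(!obj$in_depth_window),
    n_frame_reject = sum(!obj$in_frame),
    n_lipofuscin_reject = sum(obj$overlaps_lipofuscin),
    n_dual_marker_reject = sum(obj$overlaps_vglut1 & obj$overlaps_vgat),
    n_accepted = sum(obj$accepted))
  seg$objects <- obj
  seg
}

# mean of an ADU channel under each object's mask
mean_under_mask <- function(seg, channel_array, ids) {
  if (!length(ids)) return(numeric())
  pos <- which(seg$labels > 0L)
  lab <- seg$labels[pos]
  keep <- lab %in% ids
  lab <- lab[keep]
  vals <- channel_array[pos[keep]]
  out <- as.numeric(rowsum(vals, lab)) / tabulate(factor(lab, levels = sort(unique(lab))))
  setNames(out, sort(unique(lab)))[as.character(ids)]
}

#' Type accepted boutons and measure CB1R beneath their masks
#'
#' Every accepted vGlut1 object yields an excitatory bouton record and
#' every accepted vGAT object an inhibitory one; each record's `cb1r_mean`
#' is the mean of the (unenhanced, exposure-normalized) CB1R channel under
#' that object's mask. Metadata columns from `info` (subject, pair, group,
#' layer, site) are attached to every record.
#'
#' @param vglut1_seg,vgat_seg Filtered `bouton_segmentation`s (after
#'   [apply_filters()]); either may be `NULL`.
#' @param cb1r_channel 3-D array of CB1R ADU.
#' @param info A one-row tibble/list of site metadata (requires at least
#'   `subject_id`, `site_id`; typically a cohort-manifest row).
#' @return A tibble of bouton records: metadata, `terminal_type`
#'   (`vglut1`/`vgat`), `object_id`, `cb1r_mean`, `volume_um3`,
#'   `depth_corrected_um`.
#' @export
classify_terminal_type <- function(vglut1_seg, vgat_seg, cb1r_channel, info) {
  req <- c("subject_id", "site_id")
  if (is.null(info) || !all(req %in% names(info))) {
    abort("site metadata must provide subject_id and site_id (manifest row)",
          class = "boutonquant_input_error")
  }
  meta_cols <- intersect(c("subject_id", "pair_id", "group", "layer", "site_id"),
                         names(info))
  one <- function(seg, type) {
    if (is.null(seg)) return(NULL)
    acc <- seg$objects[seg$objects$accepted, ]
    if (!nrow(acc)) return(NULL)
    cb <- mean_under_mask(seg, cb1r_channel, acc$object_id)
    out <- tibble(terminal_type = type, object_id = acc$object_id,
                  cb1r_mean = as.numeric(cb), volume_um3 = acc$volume_um3,
                  depth_corrected_um = acc$depth_corrected_um,
                  x_um = acc$x_um, y_um = acc$y_um, z_um = acc$z_um)
    for (mc in rev(meta_cols)) out <- tibble::add_column(
      out, !!mc := rep(info[[mc]][[1]], nrow(out)), .before = 1)
    out
  }
  recs <- bind_rows(one(vglut1_seg, "vglut1"), one(vgat_seg, "vgat"))
  if (is.null(recs)) recs <- tibble(terminal_type = character(),
                                    object_id = integer(),
                                    cb1r_mean = double())
  recs
}

#' Split inhibitory boutons into high/low expressor classes
#'
#' Computes the split point as the median CB1R intensity of the
#' *control-group* vGAT boutons and labels every vGAT record (both groups)
#' `high` if its `cb1r_mean` exceeds the median, else `low` (ties go to
#' `low`). vGlut1 records get `NA`. The median may alternatively be taken
#' over control *subject means* (`level = "subject"`); the pooled-bouton
#' median is the default.
#'
#' @param records Bouton-record tibble from [classify_terminal_type()]
#'   (needs `group`, `terminal_type`, `cb1r_mean`; `subject_id` for the
#'   subject-level variant).
#' @param control_group Label of the control group (default `"Ctrl"`).
#' @param level `"bouton"` (pooled boutons) or `"subject"` (median of
#'   subject means).
#' @return The records with an `expressor_class` column and the split
#'   value in attribute `"split_adu"`.
#' @examples
#' r <- tibble::tibble(group = "Ctrl", terminal_type = "vgat",
#'                     cb1r_mean = c(400, 700, 2500))
#' attr(split_expressor_class(r), "split_adu") # 700
#' @export
split_expressor_class <- function(records, control_group = "Ctrl",
                                  level = c("bouton", "subject")) {
  level <- match.arg(level)
  ctrl_vgat <- records[records$group == control_group &
                         records$terminal_type == "vgat", ]
  if (!nrow(ctrl_vgat)) {
    abort("no control-group vGAT records to define the expressor split",
          class = "boutonquant_input_error")
  }
  split <- if (level == "bouton") {
    median(ctrl_vgat$cb1r_mean)
  } else {
    median(tapply(ctrl_vgat$cb1r_mean, ctrl_vgat$subject_id, mean))
  }
  records$expressor_class <- dplyr::case_when(
    records$terminal_type != "vgat" ~ NA_character_,
    records$cb1r_mean > split ~ "high",
    TRUE ~ "low")
  attr(records, "split_adu") <- split
  records
}

# middle plane of the accepted depth window, in raw plane indices
sum_plane_index <- function(geometry, filters) {
  mid_corr <- (filters$depth_min + filters$depth_max) / 2
  mid_raw <- mid_corr * geometry$measured_thickness / geometry$original_thickness
  iz <- which.min(abs(plane_depths_um(geometry) - mid_raw))
  iz
}

#' Summarize one sampled site
#'
#' Per-terminal-type unweighted mean CB1R intensity over the site's
#' accepted boutons (after expressor splitting: `vglut1`, `vgat_high`,
#' `vgat_low`), plus the site's sum CB1R intensity: the total CB1R ADU
#' under accepted CB1R-channel object masks restricted to a single 2-D
#' plane (the middle plane of the accepted depth window). Empty cells are
#' `NA`, never silently zero.
#'
#' @param records Bouton records for one site, with `expressor_class`.
#' @param cb1r_seg Filtered CB1R-channel `bouton_segmentation` (for the sum
#'   measure); `NULL` skips it.
#' @param cb1r_channel 3-D CB1R ADU array (required with `cb1r_seg`).
#' @param geometry The site's [stack_geometry()].
#' @param filters The [filter_params()] in force (locates the sum plane).
#' @param info Site metadata row (used when `records` is empty).
#' @param sum_cb1r Optional precomputed sum-CB1R value (used when the
#'   segmentation arrays are no longer held in memory); overrides
#'   `cb1r_seg`.
#' @return One-row tibble: metadata, `mean_cb1r_vglut1`,
#'   `mean_cb1r_vgat_high`, `mean_cb1r_vgat_low`, `n_vglut1`,
#'   `n_vgat_high`, `n_vgat_low`, `sum_cb1r`, `sum_plane`.
#' @export
summarize_site <- function(records, cb1r_seg = NULL, cb1r_channel = NULL,
                           geometry = NULL, filters = NULL, info = NULL,
                           sum_cb1r = NULL) {
  if (nrow(records)) {
    if (length(unique(records$site_id)) > 1) {
      abort("summarize_site expects records from a single site",
            class = "boutonquant_input_error")
    }
    meta <- records[1, intersect(c("subject_id", "pair_id", "group", "layer",
                                   "site_id"), names(records))]
  } else {
    meta <- as_tibble(info)[1, intersect(c("subject_id", "pair_id", "group",
                                           "layer", "site_id"), names(info))]
  }
  cls <- function(type, class = NULL) {
    sel <- records$terminal_type == type
    if (!is.null(class)) sel <- sel & records$expressor_class %in% class
    v <- records$cb1r_mean[sel]
    list(mean = if (length(v)) mean(v) else NA_real_, n = length(v))
  }
  ex <- cls("vglut1"); hi <- cls("vgat", "high"); lo <- cls("vgat", "low")

  plane <- NA_integer_
  if (!is.null(sum_cb1r)) {
    if (!is.null(geometry) && !is.null(filters)) {
      plane <- sum_plane_index(geometry, filters)
    }
  } else if (is.null(cb1r_seg)) {
    sum_cb1r <- NA_real_
  } else {
    stopifnot(!is.null(cb1r_channel), !is.null(geometry), !is.null(filters))
    plane <- sum_plane_index(geometry, filters)
    acc <- cb1r_seg$objects$object_id[cb1r_seg$objects$accepted]
    sl_lab <- cb1r_seg$labels[, , plane]
    sl_int <- cb1r_channel[, , plane]
    sum_cb1r <- sum(sl_int[sl_lab %in% acc])
  }
  dplyr::bind_cols(meta,
                   tibble(mean_cb1r_vglut1 = ex$mean, n_vglut1 = ex$n,
                          mean_cb1r_vgat_high = hi$mean, n_vgat_high = hi$n,
                          mean_cb1r_vgat_low = lo$mean, n_vgat_low = lo$n,
                          sum_cb1r = sum_cb1r, sum_plane = plane))
}

#' Aggregate site summaries to subject x layer values
#'
#' Unweighted mean of the site values within each subject-by-layer cell,
#' for every measure column present. Cells with no sites (or all-`NA`
#' sites for a measure) propagate as missing.
#'
#' @param site_summaries Tibble of [summarize_site()] rows.
#' @return A tibble with one row per subject x layer, the metadata columns
#'   and layer-averaged measures (`n_sites` counts contributing sites).
#' @export
summarize_layer <- function(site_summaries) {
  measures <- intersect(c("mean_cb1r_vglut1", "mean_cb1r_vgat_high",
                          "mean_cb1r_vgat_low", "sum_cb1r"),
                        names(site_summaries))
  meta <- intersect(c("pair_id", "group"), names(site_summaries))
  site_summaries |>
    group_by(dplyr::across(all_of(c("subject_id", meta, "layer")))) |>
    summarise(across(all_of(measures), ~ {
      v <- .x[!is.na(.x)]
      if (length(v)) mean(v) else NA_real_
    }), n_sites = n(), .groups = "drop")
}

#' Pivot layer summaries to the long terminal-type analysis table
#'
#' @param layer_summaries Output of [summarize_layer()].
#' @return Long tibble with `type` in `vglut1`, `vgat_high`, `vgat_low`
#'   and `value` (layer-averaged mean CB1R intensity), `NA` cells dropped.
#' @export
layer_type_table <- function(layer_summaries) {
  layer_summaries |>
    tidyr::pivot_longer(all_of(c("mean_cb1r_vglut1", "mean_cb1r_vgat_high",
                                 "mean_cb1r_vgat_low")),
                        names_to = "type", values_to = "value",
                        names_prefix = "mean_cb1r_") |>
    filter(!is.na(.data$value))
}
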