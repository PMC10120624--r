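# Iterative combined intensity/morphologic thresholding segmentation.
#
# Starting from an Otsu threshold on the DoG-enhanced channel, the
# threshold is raised in fixed gray-level increments; at each level,
# connected components inside the physical size gate are kept and unioned
# with earlier iterations (large merged blobs that split at higher
# thresholds re-enter through their fragments). The final union is
# relabeled, re-gated, and measured on the *unenhanced* intensity channel.

#' Segmentation parameters
#'
#' @param threshold_increment Gray levels added per iteration (default 50).
#' @param min_volume,max_volume Physical size gate in um^3 (defaults
#'   0.03–2.0; voxel bounds are `ceiling(min/voxel)` and
#'   `floor(max/voxel)`).
#' @param max_threshold Last threshold tried; `NULL` (default) means the
#'   channel maximum.
#' @param connectivity Voxel connectivity for 3-D labeling: 6, 18 or 26.
#' @param sparsity_floor The starting threshold is floored at the smallest
#'   gray level whose foreground occupancy does not exceed this fraction
#'   (default 0.01). Puncta and granules occupy well under 1% of tissue
#'   volume, so the floor never binds on channels with real signal; it
#'   guards against Otsu splitting the noise histogram on a channel with
#'   none. `NULL` disables.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_increment = 50, min_volume = 0.03,
                                max_volume = 2.0, max_threshold = NULL,
                                connectivity = 26, sparsity_floor = 0.01) {
  if (!isTRUE(threshold_increment > 0)) {
    abort("threshold_increment must be > 0", class = "boutonquant_param_error")
  }
  if (!(min_volume > 0 && min_volume < max_volume)) {
    abort("SegmentationParams: need 0 < min_volume < max_volume",
          class = "boutonquant_param_error")
  }
  if (!connectivity %in% c(6, 18, 26)) {
    abort("connectivity must be 6, 18 or 26", class = "boutonquant_param_error")
  }
  if (!is.null(sparsity_floor) &&
      !(sparsity_floor > 0 && sparsity_floor <= 1)) {
    abort("sparsity_floor must lie in (0, 1] or be NULL",
          class = "boutonquant_param_error")
  }
  structure(list(threshold_increment = threshold_increment,
                 min_volume = min_volume, max_volume = max_volume,
                 max_threshold = max_threshold, connectivity = connectivity,
                 sparsity_floor = sparsity_floor),
            class = "segmentation_params")
}

#' 3-D connected-component labeling
#'
#' @param mask Logical 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return Integer array of the same shape; 0 = background, components
#'   numbered from 1.
#' @export
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  stopifnot(length(d) == 3)
  lab <- .label3d_cpp(as.logical(mask), as.integer(d), as.integer(connectivity))
  dim(lab) <- d
  lab
}

#' Otsu threshold on the integer gray-level histogram
#'
#' Maximizes the between-class variance over all candidate thresholds of
#' the full-stack histogram, on integer gray levels (values are floored to
#' the camera's ADU grid). Classes are `x < t` versus `x >= t`; ties take
#' the lowest maximizing threshold.
#'
#' @param x Numeric array or vector of intensities.
#' @return The threshold gray level.
#' @export
initial_threshold <- function(x) {
  v <- floor(as.numeric(x))
  if (!all(is.finite(v))) abort("non-finite intensities", class = "boutonquant_input_error")
  lo <- min(v)
  counts <- tabulate(v - lo + 1)
  if (sum(counts > 0) < 2) {
    abort("degenerate histogram: channel has fewer than 2 distinct gray levels",
          class = "boutonquant_degenerate_error")
  }
  levels <- seq_along(counts) - 1 + lo
  counts <- as.numeric(counts)             # avoid integer overflow below
  n <- sum(counts)
  w <- cumsum(counts)                      # voxels with value <= level
  s <- cumsum(counts * levels)             # intensity mass <= level
  total <- s[length(s)]
  # threshold candidates t = levels[k + 1]: class0 = values <= levels[k]
  k <- seq_len(length(counts) - 1)
  n0 <- w[k]; n1 <- n - n0
  valid <- n0 > 0 & n1 > 0
  mu0 <- s[k] / n0
  mu1 <- (total - s[k]) / n1
  bcv <- n0 * n1 * (mu0 - mu1)^2
  bcv[!valid] <- -Inf
  levels[which.max(bcv) + 1]
}

# volume gate in voxels: conservative inclusion (ceil lower, floor upper)
volume_gate_voxels <- function(params, geometry) {
  v <- voxel_volume(geometry)
  c(lo = ceiling(params$min_volume / v),
    hi = if (is.finite(params$max_volume)) floor(params$max_volume / v) else Inf)
}

# keep only components whose voxel counts lie inside [lo, hi]
gate_labels <- function(labels, lo, hi) {
  if (max(labels) == 0) return(labels > 0)
  counts <- tabulate(labels[labels > 0L])
  ok <- counts >= lo & counts <= hi
  out <- labels > 0L
  out[out] <- ok[labels[labels > 0L]]
  out
}

#' Segment one channel by iterative multi-threshold object detection
#'
#' Runs the iterative segmentation on a DoG-enhanced channel: thresholds
#' `t = Otsu, Otsu + inc, ...` up to `max_threshold`; at each level the
#' binarized image is labeled in 3-D and components inside the size gate
#' are kept; kept voxels accumulate as a union across iterations. The
#' union is then relabeled, re-gated, and each final object is measured
#' (mean/summed ADU) on the unenhanced `intensity_channel`.
#'
#' @param enhanced_channel 3-D array, DoG-enhanced (what is thresholded).
#' @param intensity_channel 3-D array, same shape, unenhanced ADU (what is
#'   measured).
#' @param params A [segmentation_params()].
#' @param geometry The stack's [stack_geometry()].
#' @param channel Channel label recorded in the object table.
#' @return An object of class `bouton_segmentation`: list with `objects`
#'   (tibble: `object_id`, `channel`, `x_um`, `y_um`, `z_um`, `n_voxels`,
#'   `volume_um3`, `mean_adu`, `sum_adu`), `labels` (integer array) and the
#'   parameters used. An empty channel yields zero objects.
#' @export
segment_channel <- function(enhanced_channel, intensity_channel,
                            params = segmentation_params(),
                            geometry, channel = "cb1r") {
  if (!identical(dim(enhanced_channel), dim(intensity_channel))) {
    abort("enhanced and intensity channels must have the same shape",
          class = "boutonquant_input_error")
  }
  validate_geometry(geometry)
  gate <- volume_gate_voxels(params, geometry)

  union <- array(FALSE, dim(enhanced_channel))
  if (any(enhanced_channel > 0)) {
    t0 <- tryCatch(initial_threshold(enhanced_channel),
                   boutonquant_degenerate_error = function(e) NULL)
    if (!is.null(t0)) {
      if (!is.null(params$sparsity_floor)) {
        t_floor <- floor(stats::quantile(enhanced_channel,
                                         1 - params$sparsity_floor,
                                         names = FALSE)) + 1
        t0 <- max(t0, t_floor)
      }
      t_max <- params$max_threshold %||% floor(max(enhanced_channel))
      union <- .iter_union_cpp(as.numeric(enhanced_channel),
                               as.integer(dim(enhanced_channel)),
                               t0, params$threshold_increment, t_max,
                               gate[["lo"]], gate[["hi"]],
                               as.integer(params$connectivity))
      dim(union) <- dim(enhanced_channel)
    }
  }

  labels <- label_components(union, params$connectivity)
  keep <- gate_labels(labels, gate[["lo"]], gate[["hi"]])
  labels[!keep] <- 0L
  objects <- measure_labeled(labels, intensity_channel, geometry, channel)
  structure(list(objects = objects, labels = labels, channel = channel,
                 params = params, geometry = geometry),
            class = "bouton_segmentation")
}

# relabel a gated label array compactly and measure objects on an ADU channel
measure_labeled <- function(labels, intensity_channel, geometry, channel) {
  pos <- which(labels > 0L)
  if (!length(pos)) {
    labels[] <- 0L
    return(tibble(object_id = integer(), channel = character(),
                  x_um = double(), y_um = double(), z_um = double(),
                  n_voxels = integer(), volume_um3 = double(),
                  mean_adu = double(), sum_adu = double()))
  }
  old <- labels[pos]
  ids <- sort(unique(old))
  new <- match(old, ids)
  labels[pos] <- new
  d <- dim(labels)
  ix <- ((pos - 1L) %% d[1]) + 1L
  iy <- (((pos - 1L) %/% d[1]) %% d[2]) + 1L
  iz <- ((pos - 1L) %/% (d[1] * d[2])) + 1L
  vals <- intensity_channel[pos]
  nvox <- tabulate(new)
  tibble(object_id = seq_along(ids),
         channel = channel,
         x_um = as.numeric(rowsum(ix - 0.5, new)) / nvox * geometry$pixel_size_xy,
         y_um = as.numeric(rowsum(iy - 0.5, new)) / nvox * geometry$pixel_size_xy,
         z_um = (geometry$z_offset %||% 0) +
           as.numeric(rowsum(iz - 0.5, new)) / nvox * geometry$z_step,
         n_voxels = nvox,
         volume_um3 = nvox * voxel_volume(geometry),
         mean_adu = as.numeric(rowsum(vals, new)) / nvox,
         sum_adu = as.numeric(rowsum(vals, new)))
}

#' @export
print.bouton_segmentation <- function(x, ...) {
  cat(sprintf("<bouton_segmentation> channel %s: %d objects\n",
              x$channel, nrow(x$objects)))
  invisible(x)
}

#' @rdname tidy.bouton_segmentation
#' @export
tidy.bouton_segmentation <- function(x, ...) x$objects

#' Segment the lipofuscin channel into an exclusion mask
#'
#' Same iterative algorithm as [segment_channel()] but with the upper size
#' gate removed: lipofuscin aggregates routinely exceed the 2 um^3 bouton
#' maximum and must still be excluded.
#'
#' @inheritParams segment_channel
#' @param lipofuscin_channel 3-D array (enhanced lipofuscin channel).
#' @return A list with `mask` (logical array, the union exclusion mask) and
#'   `segmentation` (the underlying `bouton_segmentation`).
#' @export
segment_lipofuscin <- function(lipofuscin_channel,
                               params = segmentation_params(), geometry) {
  p <- params
  p$max_volume <- Inf
  seg <- segment_channel(lipofuscin_channel, lipofuscin_channel, p, geometry,
                         channel = "lipofuscin")
  list(mask = seg$labels > 0L, segmentation = seg)
}
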