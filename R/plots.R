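# ggplot2 views of the pipeline's result types.

#' Plot terminal-type CB1R intensity by group
#'
#' Boxplots of the subject-level (layer-averaged) mean CB1R intensity per
#' terminal-type cell and subject group — the standard view of the
#' terminal-type interaction.
#'
#' @param object A `cb1r_pipeline_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cb1r_pipeline_result <- function(object, ...) {
  subj <- object$type_table |>
    group_by(.data$subject_id, .data$group, .data$type) |>
    summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(subj, ggplot2::aes(x = .data$type, y = .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = 21, position = "dodge") +
    ggplot2::labs(x = "terminal type", y = "mean CB1R intensity (ADU)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a term table of a fitted ANCOVA
#'
#' @param object A `cb1r_ancova`.
#' @param ... Unused.
#' @return A ggplot of -log10 p per model term.
#' @export
autoplot.cb1r_ancova <- function(object, ...) {
  a <- object$anova
  ggplot2::ggplot(a, ggplot2::aes(x = stats::reorder(.data$term, .data$F),
                                  y = -log10(pmax(.data$p, 1e-16)))) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' Maximum-intensity projection of one channel with object outlines
#'
#' @param stack 4-D array `[x, y, z, channel]`.
#' @param channel Channel name.
#' @param seg Optional `bouton_segmentation`; accepted object centroids are
#'   overlaid.
#' @param geometry A [stack_geometry()] (for micron axes).
#' @return A ggplot.
#' @export
plot_projection <- function(stack, channel = "cb1r", seg = NULL,
                            geometry = NULL) {
  mip <- apply(stack[, , , channel], c(1, 2), max)
  px <- if (is.null(geometry)) 1 else geometry$pixel_size_xy
  df <- tidyr::expand_grid(x = seq_len(nrow(mip)), y = seq_len(ncol(mip))) |>
    mutate(v = mip[cbind(.data$x, .data$y)],
           x_um = (.data$x - 0.5) * px, y_um = (.data$y - 0.5) * px)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                        fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "ADU") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
  if (!is.null(seg)) {
    obj <- seg$objects
    if ("accepted" %in% names(obj)) obj <- obj[obj$accepted, ]
    if (nrow(obj)) {
      p <- p + ggplot2::geom_point(data = obj,
                                   ggplot2::aes(.data$x_um, .data$y_um),
                                   inherit.aes = FALSE, shape = 1,
                                   colour = "red")
    }
  }
  p
}
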