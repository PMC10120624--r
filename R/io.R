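# File interfaces: multi-page TIFF stacks (ZCYX page order), cohort
# manifests / truth tables as CSV, YAML configs, and stamped CSV output.

#' Write a 4-channel stack as a multi-page 16-bit TIFF
#'
#' Pages are ordered Z-major, channel-minor (ZCYX): page
#' `(z - 1) * 4 + c` holds plane `z` of channel `c` in the order vglut1,
#' cb1r, vgat, lipofuscin. Values are rounded and clamped to the 16-bit
#' range.
#'
#' @param stack 4-D numeric array `[x, y, z, channel]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack)
  stopifnot(length(d) == 4, d[4] == 4)
  pages <- vector("list", d[3] * d[4])
  i <- 1L
  for (iz in seq_len(d[3])) {
    for (k in seq_len(d[4])) {
      v <- pmin(pmax(round(stack[, , iz, k]), 0), 65535)
      # tiff stores row-major images; transpose so x runs along columns
      pages[[i]] <- t(v) / 65535
      i <- i + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_stack()]
#'
#' @param path File path.
#' @param nz Number of z planes (pages = `nz * 4`).
#' @return 4-D numeric array `[x, y, z, channel]` of ADU.
#' @export
read_stack <- function(path, nz) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) != nz * 4) {
    abort(sprintf("expected %d pages (nz * 4), found %d", nz * 4, length(pages)),
          class = "boutonquant_input_error")
  }
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  stack <- array(0, c(nx, ny, nz, 4), dimnames = list(NULL, NULL, NULL, CHANNELS))
  i <- 1L
  for (iz in seq_len(nz)) {
    for (k in 1:4) {
      stack[, , iz, k] <- t(pages[[i]])
      i <- i + 1L
    }
  }
  stack
}

#' Write a synthetic cohort to disk
#'
#' Realizes every site of the cohort and writes one multi-page TIFF per
#' site plus `manifest.csv` and `truth.csv` (all ground-truth objects,
#' with site ids). Coordinates are exported in microns; voxel indices used
#' internally are 0-based at voxel centers, as noted in the file header.
#'
#' @param cohort A `synthetic_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truths <- vector("list", nrow(cohort$manifest))
  for (i in seq_len(nrow(cohort$manifest))) {
    site <- generate_site(cohort, i)
    write_stack(site$stack, file.path(out_dir, paste0(site$info$site_id, ".tif")))
    truths[[i]] <- site$truth
  }
  write_stamped_csv(cohort$manifest, file.path(out_dir, "manifest.csv"),
                    seed = cohort$seed)
  write_stamped_csv(bind_rows(truths), file.path(out_dir, "truth.csv"),
                    seed = cohort$seed)
  invisible(out_dir)
}

#' Write a CSV with a provenance header
#'
#' Prepends `#`-comment lines carrying a content hash of the generating
#' configuration and the seed, then the data as plain CSV. Columns in
#' microns are named `*_um`; voxel indices are 0-based at voxel centers.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param config Optional configuration object hashed into the header.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_stamped_csv <- function(x, path, config = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# boutonquant v%s", as.character(utils::packageVersion("boutonquant"))),
    sprintf("# config_hash: %s", if (is.null(config)) "none" else rlang::hash(config)),
    sprintf("# seed: %s", if (is.null(seed)) "none" else seed),
    "# coordinates in um; voxel indices 0-based at voxel centers"), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' Read a stamped CSV back
#'
#' @param path Path written by [write_stamped_csv()].
#' @return A tibble (header comments skipped).
#' @export
read_stamped_csv <- function(path) {
  as_tibble(utils::read.csv(path, comment.char = "#"))
}
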