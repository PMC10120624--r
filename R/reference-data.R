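# Published reference values shipped as code-constructed tibbles. These
# are the printed inputs the worked examples and acceptance checks run on:
# per-pair reciprocal assay ratios from the prior studies of the same
# cohort, the terminal-type group means, and the cohort demographics.

#' Reference per-pair reciprocal assay ratios
#'
#' The ten matched pairs' previously published SZ/Ctrl ratios: CB1R
#' protein by immunohistochemistry (optical density) and CB1R
#' ligand-binding (OMAR, fm/mg), both in percent. Feed into
#' [build_pair_ratio_table()] to reproduce the magnitude differences and
#' column summaries.
#'
#' @return Tibble: `pair_id`, `ihc_ratio_pct`, `ligand_ratio_pct`.
#' @export
reference_pair_ratios <- function() {
  tibble(pair_id = 1:10,
         ihc_ratio_pct = c(-5.57, -11.04, -20.18, -31.61, -24.01,
                           -6.17, -30.19, -23.15, -14.64, -21.75),
         ligand_ratio_pct = c(25.76, 41.18, 2.51, 74.85, -0.74,
                              29.19, 43.08, -5.18, 47.74, 14.52))
}

#' Reference terminal-type group means
#'
#' Published mean CB1R intensity (ADU) per terminal-type cell and subject
#' group (pooled SEM 48.073 ADU). These are the default generating cell
#' means of [sim_params()].
#'
#' @return Tibble: `type`, `group`, `mean_adu`, `sem_adu`.
#' @export
reference_group_means <- function() {
  tidyr::expand_grid(type = c("vglut1", "vgat_high", "vgat_low"),
                     group = c("Ctrl", "SZ")) |>
    mutate(mean_adu = c(770.537, 1042.193, 2510.098, 2137.309,
                        435.461, 460.420),
           sem_adu = 48.073)
}

#' Reference cohort demographics
#'
#' Group-level demographic summaries of the ten matched pairs: counts for
#' the categorical variables and mean (SD) for the continuous ones.
#'
#' @return A list with `categorical` (tibble: `variable`, `level`,
#'   `ctrl_n`, `sz_n`) and `continuous` (tibble: `variable`, `ctrl_mean`,
#'   `ctrl_sd`, `sz_mean`, `sz_sd`).
#' @export
reference_demographics <- function() {
  list(
    categorical = tibble(
      variable = c("sex", "sex", "race", "race",
                   "cannabis_use", "cannabis_use"),
      level = c("Female", "Male", "Black", "White", "Yes", "No"),
      ctrl_n = c(1, 9, 2, 8, 0, 10),
      sz_n = c(1, 9, 1, 9, 3, 7)),
    continuous = tibble(
      variable = c("age_years", "pmi_hours", "storage_months", "ph"),
      ctrl_mean = c(46.9, 17.9, 187.8, 6.96),
      ctrl_sd = c(15.9, 5.9, 16.3, 0.24),
      sz_mean = c(48.4, 20.3, 188.8, 6.92),
      sz_sd = c(13.7, 11.2, 24.4, 0.20)))
}
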