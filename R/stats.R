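# Study-level statistics: Type III ANCOVA with pair blocking or covariate
# adjustment, Bonferroni post hocs, within-pair ratio t tests, demographic
# comparisons, and the reciprocal-ratio arithmetic.

#' Specify an ANCOVA model
#'
#' The paired variant enters subject pair as a fixed blocking factor; the
#' unpaired variant replaces blocking with the cohort covariates (sex,
#' race, age, postmortem interval, storage time). The two are mutually
#' exclusive.
#'
#' @param response Name of the response column.
#' @param fixed Character vector of fixed-effect terms (factors and `:`
#'   interactions), e.g. `c("group", "layer", "group:layer")`.
#' @param blocking Optional blocking factor column name (e.g. `"pair_id"`).
#' @param covariates Optional character vector of covariate columns.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response, fixed, blocking = NULL, covariates = NULL) {
  if (!is.null(blocking) && !is.null(covariates)) {
    abort("a model uses either a blocking factor (paired) or covariates (unpaired), not both",
          class = "boutonquant_param_error")
  }
  structure(list(response = response, fixed = fixed, blocking = blocking,
                 covariates = covariates), class = "model_spec")
}

#' Fit an ANCOVA and test terms with Type III sums of squares
#'
#' Ordinary least squares with sum-to-zero contrasts on every factor;
#' per-term F tests use Type III sums of squares (the convention matching
#' `F(df_num, df_den)` reporting). Character/logical columns among the
#' model variables are converted to factors; the blocking factor is always
#' treated as a factor.
#'
#' @param data A data frame / tibble in long format.
#' @param spec A [model_spec()].
#' @return An object of class `cb1r_ancova`: list with `anova` (tibble:
#'   `term`, `F`, `df_num`, `df_den`, `p`), the underlying `fit`, and
#'   `spec`. Use [tidy()] / [glance()] / [posthoc_bonferroni()].
#' @examples
#' d <- sim_measurement_table(sim_params(n_pairs = 4), layers = "III", seed = 1)
#' fit <- fit_ancova(d, model_spec("value",
#'                                 c("group", "type", "group:type"),
#'                                 blocking = "pair_id"))
#' tidy(fit)
#' @export
fit_ancova <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  base_vars <- unique(unlist(strsplit(spec$fixed, ":", fixed = TRUE)))
  rhs <- c(spec$fixed,
           if (!is.null(spec$blocking)) spec$blocking,
           spec$covariates)
  vars <- unique(c(spec$response, base_vars, spec$blocking, spec$covariates))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    abort(paste("model columns not in data:", paste(missing_cols, collapse = ", ")),
          class = "boutonquant_input_error")
  }
  d <- as.data.frame(data[, vars])
  n0 <- nrow(d)
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < n0) {
    rlang::inform(sprintf("dropped %d incomplete rows before fitting", n0 - nrow(d)))
  }
  for (v in setdiff(vars, spec$response)) {
    if (is.character(d[[v]]) || is.logical(d[[v]]) ||
        identical(v, spec$blocking)) {
      d[[v]] <- factor(d[[v]])
    }
  }
  # a covariate constant in this cohort carries no information; drop it
  for (v in spec$covariates) {
    if (is.factor(d[[v]]) && nlevels(droplevels(d[[v]])) < 2) {
      rlang::inform(sprintf("covariate '%s' is constant; dropped", v))
      spec$covariates <- setdiff(spec$covariates, v)
      rhs <- setdiff(rhs, v)
      d[[v]] <- NULL
    }
  }
  fac <- names(d)[vapply(d, is.factor, TRUE)]
  contr <- setNames(rep(list("contr.sum"), length(fac)), fac)

  form <- as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")))
  degenerate <- var(d[[spec$response]]) == 0
  fit <- lm(form, data = d, contrasts = contr)

  al <- alias(fit)$Complete
  if (!is.null(al)) {
    abort(paste("rank-deficient design; aliased coefficients:",
                paste(rownames(al), collapse = ", ")),
          class = "boutonquant_model_error")
  }

  if (degenerate) {
    warn("response is constant; all F statistics are degenerate (reported as 0)")
    terms_tested <- rhs
    out <- tibble(term = terms_tested, F = 0, df_num = NA_integer_,
                  df_den = fit$df.residual, p = 1)
  } else {
    a3 <- car::Anova(fit, type = 3)
    keep <- !rownames(a3) %in% c("(Intercept)", "Residuals")
    out <- tibble(term = rownames(a3)[keep],
                  F = a3[keep, "F value"],
                  df_num = as.integer(a3[keep, "Df"]),
                  df_den = as.integer(fit$df.residual),
                  p = a3[keep, "Pr(>F)"])
  }
  structure(list(anova = out, fit = fit, spec = spec, data = d),
            class = "cb1r_ancova")
}

#' @export
print.cb1r_ancova <- function(x, ...) {
  cat("<cb1r_ancova>", x$spec$response, "~",
      paste(c(x$spec$fixed, x$spec$blocking, x$spec$covariates), collapse = " + "), "\n")
  a <- x$anova
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  %-28s F(%s,%d) = %8.3f  p = %.4g\n", a$term[i],
                ifelse(is.na(a$df_num[i]), "?", a$df_num[i]), a$df_den[i],
                a$F[i], a$p[i]))
  }
  invisible(x)
}

#' Tidy methods for fitted objects and segmentations
#'
#' @param x A `cb1r_ancova` or `bouton_segmentation`.
#' @param ... Unused.
#' @return A tibble (the term table, or the object table).
#' @name tidy.bouton_segmentation
NULL

#' @rdname tidy.bouton_segmentation
#' @export
tidy.cb1r_ancova <- function(x, ...) x$anova

#' @rdname tidy.bouton_segmentation
#' @export
glance.cb1r_ancova <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
         sigma = s$sigma, df_residual = x$fit$df.residual,
         nobs = nrow(x$data))
}

#' Bonferroni adjustment
#'
#' @param p Raw p values.
#' @param k Number of comparisons (`>= 1`).
#' @return `min(1, p * k)`, elementwise.
#' @export
bonferroni_adjust <- function(p, k) {
  if (!isTRUE(k >= 1)) abort("k must be >= 1", class = "boutonquant_param_error")
  pmin(1, p * k)
}

#' Bonferroni post hoc group contrasts from a fitted ANCOVA
#'
#' Pairwise group contrasts of model cell means within each level of `by`
#' (e.g. group within terminal type), using the model residual variance,
#' Bonferroni-adjusted across the family.
#'
#' @param fit A `cb1r_ancova`.
#' @param specs Factor whose levels are contrasted (default `"group"`).
#' @param by Optional conditioning factor (default `"type"` if present in
#'   the model, else none).
#' @param k Number of comparisons for the adjustment; default is the
#'   family size emmeans reports.
#' @return Tibble: `contrast`, `by` level, `estimate`, `t`, `df`, `p`,
#'   `adjusted_p`.
#' @export
posthoc_bonferroni <- function(fit, specs = "group", by = NULL, k = NULL) {
  stopifnot(inherits(fit, "cb1r_ancova"))
  if (is.null(by) && "type" %in% names(fit$data)) by <- "type"
  em <- emmeans::emmeans(fit$fit, specs = specs, by = by)
  ct <- summary(emmeans::contrast(em, method = "pairwise", adjust = "none"),
                infer = c(FALSE, TRUE))
  k <- k %||% nrow(ct)
  out <- as_tibble(ct) |>
    rename(t = "t.ratio", p = "p.value") |>
    mutate(adjusted_p = bonferroni_adjust(.data$p, k))
  out
}

#' Percent group difference
#'
#' @param mean_sz,mean_ctrl Group means (control must be positive).
#' @return `100 * (mean_sz - mean_ctrl) / mean_ctrl`.
#' @examples
#' group_percent_difference(1042.193, 770.537) # +35.3
#' @export
group_percent_difference <- function(mean_sz, mean_ctrl) {
  if (any(mean_ctrl <= 0)) {
    abort("control mean must be > 0", class = "boutonquant_param_error")
  }
  100 * (mean_sz - mean_ctrl) / mean_ctrl
}

#' Compare within-pair intensity ratios between exposure groups
#'
#' Pooled-variance (Student) two-tailed t test of per-pair Ctrl/SZ
#' intensity ratios between pairs whose SZ member has, versus has not, a
#' given exposure history (cannabis, medication).
#'
#' @param ratios Numeric vector of within-pair ratios.
#' @param exposed Logical vector, same length: exposure history of the
#'   pair's SZ member.
#' @return Tibble: `t`, `df`, `p`, `mean_exposed`, `mean_unexposed`,
#'   `n_exposed`, `n_unexposed`.
#' @export
within_pair_ratio_test <- function(ratios, exposed) {
  stopifnot(length(ratios) == length(exposed))
  exposed <- as.logical(exposed)
  n1 <- sum(exposed); n0 <- sum(!exposed)
  if (n1 == 0 || n0 == 0) {
    abort("both exposure groups must be nonempty", class = "boutonquant_input_error")
  }
  if (min(n1, n0) == 1) {
    warn("an exposure group has n = 1; pooled-variance t is defined but fragile")
  }
  if (n1 + n0 < 3) {
    warn("fewer than 3 pairs in total; no residual df for a pooled t test")
    return(tibble(t = NA_real_, df = 0, p = NA_real_,
                  mean_exposed = mean(ratios[exposed]),
                  mean_unexposed = mean(ratios[!exposed]),
                  n_exposed = n1, n_unexposed = n0))
  }
  tt <- t.test(ratios[exposed], ratios[!exposed], var.equal = TRUE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, mean_exposed = mean(ratios[exposed]),
         mean_unexposed = mean(ratios[!exposed]),
         n_exposed = n1, n_unexposed = n0)
}

#' Reciprocal ligand-binding / IHC ratio table
#'
#' Builds the per-pair table of IHC protein SZ/Ctrl ratios, ligand-binding
#' SZ/Ctrl ratios and their magnitude difference (ligand minus protein),
#' in percent. [glance()] returns the column means and sample SDs.
#'
#' @param ihc_ratios,ligand_ratios Equal-length numeric vectors (percent).
#' @param pair_id Optional pair identifiers.
#' @return A tibble of class `pair_ratio_table` with columns `pair_id`,
#'   `ihc_ratio_pct`, `ligand_ratio_pct`, `magnitude_difference`.
#' @examples
#' tab <- build_pair_ratio_table(c(-5.57, -11.04), c(25.76, 41.18))
#' tab$magnitude_difference # 31.33 52.22
#' @export
build_pair_ratio_table <- function(ihc_ratios, ligand_ratios,
                                   pair_id = seq_along(ihc_ratios)) {
  if (length(ihc_ratios) != length(ligand_ratios)) {
    abort("ratio lists must have equal length", class = "boutonquant_input_error")
  }
  out <- tibble(pair_id = pair_id, ihc_ratio_pct = ihc_ratios,
                ligand_ratio_pct = ligand_ratios,
                magnitude_difference = ligand_ratios - ihc_ratios)
  class(out) <- c("pair_ratio_table", class(out))
  out
}

#' @rdname tidy.bouton_segmentation
#' @export
glance.pair_ratio_table <- function(x, ...) {
  tibble(ihc_mean = mean(x$ihc_ratio_pct), ihc_sd = sd(x$ihc_ratio_pct),
         ligand_mean = mean(x$ligand_ratio_pct), ligand_sd = sd(x$ligand_ratio_pct),
         magnitude_mean = mean(x$magnitude_difference),
         magnitude_sd = sd(x$magnitude_difference),
         n_pairs = nrow(x))
}

#' Demographic group comparisons
#'
#' Fisher's exact test for categorical variables and pooled-variance
#' (Student) two-tailed t tests for continuous variables, comparing the
#' two subject groups of a cohort manifest. Empty category levels are
#' dropped with a warning.
#'
#' @param subjects Subject-level tibble with a `group` column; every other
#'   supplied variable is tested.
#' @param variables Columns to test; default: all columns except
#'   identifiers (`subject_id`, `pair_id`, `group`).
#' @return Tibble: `variable`, `test` (`fisher`/`t`), `statistic` (t value
#'   or `NA` for Fisher), `p`.
#' @export
demographic_tests <- function(subjects,
                              variables = setdiff(names(subjects),
                                                  c("subject_id", "pair_id", "group"))) {
  if (length(unique(subjects$group)) != 2) {
    abort("exactly two groups are required", class = "boutonquant_input_error")
  }
  rows <- purrr::map(variables, function(v) {
    x <- subjects[[v]]
    if (is.numeric(x)) {
      tt <- t.test(x ~ subjects$group, var.equal = TRUE)
      tibble(variable = v, test = "t", statistic = unname(tt$statistic),
             p = tt$p.value)
    } else {
      x <- factor(x)
      if (any(table(x) == 0)) {
        warn(sprintf("dropping empty levels of %s", v))
        x <- droplevels(x)
      }
      if (nlevels(x) < 2) {
        return(tibble(variable = v, test = "fisher", statistic = NA_real_,
                      p = NA_real_))
      }
      ft <- fisher.test(table(subjects$group, x))
      tibble(variable = v, test = "fisher", statistic = NA_real_, p = ft$p.value)
    }
  })
  bind_rows(rows)
}
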