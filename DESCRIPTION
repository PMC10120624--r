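Package: boutonquant
Title: Terminal-Type-Specific Quantification of Presynaptic CB1 Receptor
    in 3-D Confocal Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying cannabinoid CB1
    receptor (CB1R) immunofluorescence within excitatory (vGlut1) and
    inhibitory (vGAT) presynaptic boutons in multichannel 3-D confocal
    image stacks of postmortem cortex. Provides a synthetic-stack
    generator with ground truth for validation, exposure normalization
    and difference-of-Gaussians spot enhancement, iterative
    multi-threshold size-gated segmentation with 3-D connected-component
    labeling, lipofuscin autofluorescence masking, colocalization-based
    terminal typing with high/low expressor splitting at the control
    median, site and layer aggregation, and the study-level statistics:
    paired (pair-blocked) and covariate-adjusted ANCOVA with Type III
    sums of squares, Bonferroni post hocs, within-pair ratio t tests,
    and demographic comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    dplyr,
    EBImage,
    emmeans,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
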