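# boutonquant

Terminal-type-specific quantification of presynaptic cannabinoid CB1
receptor (CB1R) immunofluorescence in multichannel 3-D confocal stacks of
postmortem cortex — segmentation, colocalization-based typing, and the
cohort-level statistics, with a ground-truthed synthetic-stack generator
for validation.

## The problem

CB1R suppresses neurotransmitter release from the presynaptic side. In
human prefrontal cortex it is enriched in a subset of inhibitory
(vGAT-positive, presumptively cholecystokinin-type) boutons and present at
lower levels in excitatory (vGlut1-positive) boutons. Bulk assays
disagree about CB1R in schizophrenia — ligand binding (which sees all
CB1R) reports increases, while certain antibodies (which preferentially
see the high-expressing inhibitory pool) report decreases. The
reconciliation requires measuring CB1R *per terminal type*:

* segment each marker channel with an iterative multi-threshold
  algorithm: starting at Otsu's threshold on a difference-of-Gaussians
  (σ 0.7 − σ 2.0 px) enhanced channel, raise the threshold in 50
  gray-level steps, keep 3-D connected components with volume in
  0.03–2.0 µm³, and union the kept voxels across levels;
* copy the final masks back onto the unenhanced CB1R channel and take
  the mean ADU under each mask;
* reject objects outside the 10–14 µm shrinkage-corrected depth window
  or the 2% XY guard frame (pixels 10–502 at 512 px), overlapping the
  lipofuscin autofluorescence mask, or overlapping both marker masks;
* split inhibitory boutons into high/low expressors at the control-group
  median CB1R intensity;
* average boutons → sites → cortical layers, and fit Type III ANCOVA
  models: fixed effects of subject group, layer, terminal type and their
  interactions, with subject pair as a blocking factor (paired model) or
  sex/race/age/PMI/storage time as covariates (unpaired model), followed
  by Bonferroni-adjusted group contrasts, within-pair ratio t tests
  against exposure histories, and Fisher/Student demographics.

Because no raw tissue stacks are publicly deposited, the package ships a
synthetic cohort generator (`generate_stack()`, `generate_cohort()`)
producing 4-channel stacks with exact per-object ground truth — bouton
positions, sizes and true mean CB1R values drawn from the published
terminal-type cell means — so every pipeline stage is testable.

## Worked example

```r
library(boutonquant)

cfg <- pipeline_config(
  sim = sim_params(n_pairs = 10),              # published cell means by default
  geometry = stack_geometry(nx = 96, ny = 96, nz = 18, z_offset = 6),
  layers = "III", sites_per_layer = 3, seed = 1)
res <- run_pipeline(cfg)
res
```

```
<cb1r_pipeline_result> 60 sites, 298 boutons (split at 1599.0 ADU)
  vgat_high  SZ vs Ctrl: -16.9%
  vgat_low   SZ vs Ctrl: +1.1%
  vglut1     SZ vs Ctrl: +37.8%
  group x type interaction: F(2,44) = 72.409, p = 1.21e-14
```

The cohort was generated with a +35.3% excitatory effect and a −14.9%
high-inhibitory effect (the published group differences); this single
seed recovers them with the sampling error expected from 10 pairs × 3
sites, detects the terminal-type-by-group interaction, and places the
expressor split (1599 ADU) in the gap between the low and high vGAT
intensity modes. `tidy(res$fits$paired_type)` returns the Type III F
table, `res$posthoc` the Bonferroni contrasts, `autoplot(res)` the
terminal-type box plot, and `res$attrition` the per-site object counts
through each filter.

Reference tables used by the examples and checks are shipped as code:
`reference_pair_ratios()` (per-pair IHC and ligand-binding SZ/Ctrl
ratios), `reference_group_means()` (terminal-type cell means, ADU) and
`reference_demographics()` (cohort demographics).

## Package tour

| Stage | Functions |
|---|---|
| synthetic data | `sim_params()`, `generate_stack()`, `generate_cohort()`, `generate_site()`, `truth_object()`, `render_truth()`, `sim_measurement_table()` |
| image processing | `normalize_exposure()`, `correct_z_shrinkage()`, `difference_of_gaussians()`, `enhance_stack()` |
| segmentation | `initial_threshold()`, `segment_channel()`, `segment_lipofuscin()`, `label_components()`, `voxel_volume()` |
| measurement | `apply_filters()`, `classify_terminal_type()`, `split_expressor_class()`, `summarize_site()`, `summarize_layer()` |
| statistics | `fit_ancova()`, `posthoc_bonferroni()`, `group_percent_difference()`, `within_pair_ratio_test()`, `build_pair_ratio_table()`, `demographic_tests()` |
| pipeline & I/O | `pipeline_config()`, `validate_config()`, `run_pipeline()`, `write_results()`, `write_stack()` / `read_stack()`, `write_cohort()`, `read_config()` |

All tabular results are tibbles; fitted models support `tidy()` /
`glance()`; result objects have `autoplot()` methods. The methods
vignette (`vignettes/terminal-type-cb1r-quantification.Rmd`) documents
the generative model, the crowding and mode-separation criteria behind
the simulation defaults, numerical conventions, and known limitations.
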