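---
title: "Quantifying terminal-type-specific CB1 receptor levels in confocal stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying terminal-type-specific CB1 receptor levels in confocal stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boutonquant)
```

## The measurement problem

The cannabinoid CB1 receptor (CB1R) sits presynaptically and suppresses
neurotransmitter release when activated. In human prefrontal cortex it is
present both in inhibitory boutons (vGAT-positive; highest in the
cholecystokinin interneuron subtype) and, at lower levels, in excitatory
boutons (vGlut1-positive). Because ligand-binding assays see *all* CB1R
while many antibodies preferentially see the high-expressing inhibitory
pool, bulk comparisons between schizophrenia (SZ) and control (Ctrl)
tissue have produced apparently contradictory results. Resolving the
contradiction requires quantifying CB1R *per terminal type*: segment
vGlut1 and vGAT boutons in multichannel 3-D confocal stacks, measure mean
CB1R intensity (in camera ADU) under each bouton mask, split inhibitory
boutons into high/low expressors at the control-group median, aggregate
to sampling sites and cortical layers, and compare groups with
pair-blocked ANCOVA.

`boutonquant` implements that pipeline end to end, together with a
synthetic-stack generator whose ground truth lets every stage be
validated without access to tissue.

## The processing pipeline

For each acquired site (a 4-channel stack: vGlut1, CB1R, vGAT,
lipofuscin):

1. **Exposure normalization** (`normalize_exposure()`): each channel is
   scaled by `reference / exposure` so captures taken at per-site optimal
   exposures are comparable. The reference is the nominal exposure set
   recorded in the configuration.
2. **Spot enhancement** (`difference_of_gaussians()`): a band-pass
   `G(0.7 px) − G(2.0 px)`, applied slice-wise in XY, enhances punctate
   structure; negative responses are clipped to zero. The slice-wise
   (2-D) choice mirrors the channel arithmetic of the acquisition
   software the workflow descends from; a 3-D variant is available via
   `enhancement_params(dims = 3)`.
3. **Iterative segmentation** (`segment_channel()`): starting from Otsu's
   threshold on the enhanced channel, the threshold rises in 50-gray-level
   steps to the channel maximum. At each level, 26-connected 3-D
   components with volume inside 0.03–2.0 µm³ are kept and unioned across
   levels (so merged aggregates that split at higher thresholds re-enter
   through their in-gate fragments). The final union is relabeled,
   re-gated, and measured on the *unenhanced* channel. Two numerical
   conventions: the µm³→voxel gate uses `ceiling` for the minimum and
   `floor` for the maximum (conservative inclusion), and Otsu ties across
   empty histogram gaps resolve to the lowest gray level.
4. **Lipofuscin exclusion** (`segment_lipofuscin()`): the same algorithm
   without the upper size gate — autofluorescent lysosomal aggregates
   routinely exceed the bouton gate and must still be masked. Because a
   channel that happens to contain no aggregates would otherwise hand
   Otsu a pure-noise histogram (whose near-zero split percolates into one
   giant component), the starting threshold is floored at the smallest
   gray level with ≤ 1% foreground occupancy; genuine puncta and granules
   occupy far less than 1% of tissue volume, so the floor never binds
   when signal exists.
5. **Acceptance filters** (`apply_filters()`): an object is kept only if
   its shrinkage-corrected centroid depth lies in 10–14 µm below the
   tissue surface (the zone of uniform antibody penetrance; raw depths
   are multiplied by `40 / measured thickness`), its centroid lies inside
   a counting frame excluding the outer 2% of the XY field (pixels
   10–502 on a 512-pixel frame), no voxel overlaps the lipofuscin mask,
   and it does not overlap *both* marker masks (ambiguous dual-labeled
   objects). The filters are independent flags, so their order is
   irrelevant and re-application is idempotent.
6. **Terminal typing** (`classify_terminal_type()`): every accepted
   vGlut1 (vGAT) object becomes an excitatory (inhibitory) bouton record
   whose `cb1r_mean` is the mean of the unenhanced CB1R channel under the
   marker mask.
7. **Expressor split** (`split_expressor_class()`): inhibitory records
   are labeled `high` if `cb1r_mean` exceeds the median CB1R intensity of
   control-group vGAT boutons, `low` otherwise (ties low). Both variants
   of the control median are implemented — pooled boutons and the median
   of subject means. The *function* default is the pooled-bouton median;
   the *pipeline* default is the subject-mean median, for a reason worth
   spelling out: when the within-subject distribution is strongly
   bimodal, the pooled median is an order statistic that necessarily
   falls inside one of the two mode clusters, and its sampling error
   reassigns gap-edge boutons between classes — on small cohorts this
   inflates the low-expressor mean unpredictably. Every subject's vGAT
   *mean*, in contrast, sits between the modes, so their median is a
   stable gap statistic.
8. **Aggregation** (`summarize_site()`, `summarize_layer()`): unweighted
   bouton→site and site→layer means per terminal-type cell; sum CB1R
   intensity is the total CB1R ADU under accepted CB1R-channel object
   masks restricted to a single 2-D plane. The plane is the one nearest
   the middle of the accepted depth window (corrected 12 µm); nothing in
   the upstream protocol pins down which plane was used originally, and
   the window midpoint is the least arbitrary choice.
9. **Statistics** (`fit_ancova()` and friends): Type III sums of squares
   with sum-to-zero contrasts (the convention that matches
   `F(df1, df2)`-style reporting). The paired variant blocks on subject
   pair as a fixed factor; the unpaired variant instead adjusts for sex,
   race, age, postmortem interval and storage time (factor covariates
   that are constant in a cohort are dropped with a message). Group
   contrasts within terminal type use the model residual variance with
   Bonferroni adjustment (`posthoc_bonferroni()`); within-pair Ctrl/SZ
   intensity ratios are compared between exposure histories with a
   pooled-variance t test; demographics use Fisher's exact test and
   Student's t.

Pair is treated as a fixed blocking factor, not a random effect, and
degrees of freedom are reported exactly as computed. Missing
subject-by-layer-by-type cells (no accepted boutons of a type) are
dropped listwise with a message. In the unpaired model, factor
covariates use indicator coding against the most frequent level.

## The synthetic cohort generator

`generate_stack()` renders scenes of four object classes into a
calibrated voxel grid (default 512×512 pixels at 55/512 µm, 0.25 µm z
steps): vGlut1 and vGAT boutons, non-synaptic CB1R puncta, and
lipofuscin granules (broad-spectrum: rendered into all four channels).
Marker and non-synaptic signals are anisotropic 3-D Gaussians with
σ~z~ = 2 σ~xy~. The CB1R signal *inside* a bouton is rendered as a
uniform plateau over the bouton support (r ≤ 2.25 in σ-normalized units,
soft Gaussian edge): receptor fluorescence fills the terminal, and —
decisively for validation — a uniform fill is the only profile under
which "mean intensity under the mask" has a scalar ground truth that
does not depend on exactly where the segmented mask ends. The recorded
`cb1r_mean_truth` is that plateau value times the depth-attenuation
factor at the bouton center.

Signal attenuates with raw depth as
`exp(−rate × (depth − window mid))`, referenced to the middle of the
10–14 µm analysis window: the window was chosen in the original
workflow precisely because penetrance is flat there, and per-capture
exposure optimization rescales overall brightness anyway, so the
attenuation acts as a gradient rather than a global bias. Per-voxel
noise is Gaussian with variance `σ²~read~ + s × signal`
(read + shot). `generate_cohort()` draws matched pairs (shared sex,
similar age), per-subject measured thickness (shrinkage), per-site
jittered optimal exposures (lipofuscin at constant exposure), covariates
typical of a middle-aged postmortem cohort, and one reproducible seed
per site, so any site regenerates independently.

### Free parameters and the crowding budget

The study this design follows reports no bouton densities, spot sizes or
noise figures, so those generator defaults are the package's own — and
they are chosen *for testability, not tissue fidelity*. Two explicit
criteria fix them:

* **Crowding budget.** The mean CB1R a mask picks up from *other*
  objects' footprints is roughly
  Σ (density × footprint integral × mean intensity). At the defaults
  (6/12/5 boutons per 1000 µm³ for vGlut1/vGAT/non-synaptic, 2
  lipofuscin, σ~xy~ 0.15–0.25 µm) this contamination stays near 2% of
  the excitatory cell mean, small enough that recovered cell means can
  be compared with generating ones at the 5% level. Real cortical
  neuropil is 1–2 orders of magnitude denser; in real tissue the
  measured means are *defined* with this crowding included.
* **Mode-separation criterion.** The high/low expressor classes are only
  recoverable by a median split if the split point stays ≥ 3 combined
  standard deviations (bouton lognormal spread ⊕ subject scale ⊕ split
  sampling error) away from both vGAT modes in both groups. The binding
  case is the SZ high mode (2137 ADU vs an expected split near 1470),
  which forces `intensity_cv = 0.10` and `subject_cv = 0.05` — tighter
  than the between-subject spread the published SEMs imply (≈ 0.15–0.2).

Both criteria are deliberate idealizations. Passing recovery tests
therefore demonstrates that the pipeline is unbiased and well calibrated
*when its assumptions hold*; it does not certify performance on crowded,
high-variance real tissue, where the segmentation-merge behavior and the
median split both degrade first.

### What the generator does not emulate

Optics (no PSF: stacks represent post-deconvolution images), spectral
bleed-through other than lipofuscin, laminar cytoarchitecture (layer
labels come from the manifest), soma/axonal CB1R morphology (the
non-colocalized pool is punctate), and saturation/vignetting.

## Simulation scales used in validation

The shipped checks run at reduced problem sizes chosen as a deliberate
compromise between sampling error and runtime on a single CPU: recovery
cohorts use 10 pairs × 1 layer × 3 sites × 96×96×18-voxel stacks
acquired from 6 µm depth (`z_offset`), which covers the corrected
10–14 µm analysis window; 20 seeds for recovery and detection; 200
table-level replicates (via `sim_measurement_table()`, which simulates
the layer-aggregated measurement distribution directly) for null
calibration of the group test; 24 noise-free stacks for segmentation
recall/false-discovery, with both truth and detections restricted to
the pipeline's acceptance region (counting frame plus corrected depth
window) so that objects truncated at the faces of the reduced
acquisition band do not masquerade as segmentation misses. Sum-CB1R
measurement is exercised in the pipeline tests rather than the recovery
loop.

## Known limitations

* The union-then-relabel merge rule means boutons closer than roughly
  4σ (laterally) or 2σ~z~ (axially) can fuse into one object; at
  realistic densities this is the dominant segmentation error mode.
* A bright aggregate always contributes a sub-gate core fragment to the
  bouton channels at high thresholds; the lipofuscin and dual-marker
  exclusions are what keep such fragments out of the analysis.
* The median split assigns the lower tail of the high-expressor
  population to the low class whenever the modes overlap the split;
  with realistic spread this biases the low-expressor cell upward — a
  property of the method itself, not of the implementation.
* Pair is a fixed block; with many missing cells a mixed model would
  use the data more efficiently but would not match the reported
  F-statistic layout.
* The fixed-effects ANCOVA treats a subject's three terminal-type cells
  as independent observations (the convention of the original design).
  When a subject-level random intensity scale is present — as the
  generator's defaults include — the group test is anticonservative
  (measured type-I rate ≈ 0.2 at a 5% subject CV). The shipped
  calibration check therefore simulates with the subject scale off,
  verifying the implementation under the model's own assumptions; users
  analyzing data with substantial between-subject technical variation
  should treat group main-effect p values with corresponding caution or
  move to a mixed model.

## A worked example

```{r example, eval = FALSE}
library(boutonquant)

cfg <- pipeline_config(
  sim = sim_params(n_pairs = 10),
  geometry = stack_geometry(nx = 96, ny = 96, nz = 18, z_offset = 6),
  layers = "III", sites_per_layer = 3, seed = 1)
res <- run_pipeline(cfg)

res$percent_differences      # estimated SZ vs Ctrl, per terminal type
tidy(res$fits$paired_type)   # Type III F table, pair-blocked
res$posthoc                  # Bonferroni group contrasts within type
autoplot(res)                # the terminal-type box plot
```
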