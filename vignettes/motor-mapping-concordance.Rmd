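---
title: "Quantifying concordance of resting-state and task fMRI motor maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying concordance of resting-state and task fMRI motor maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motormap)
```

## The problem

In presurgical planning for lesions near the central sulcus, the motor
cortex is classically localized with task-based fMRI (tb-fMRI): the patient
performs hand, foot or mouth movements in a block design and a GLM yields a
t-map of task-locked activation. Patients who cannot perform the task
reliably motivate resting-state fMRI (rs-fMRI), which maps the sensorimotor
network from spontaneous low-frequency BOLD fluctuations, either by
seed-based analysis (SBA) or by spatial independent component analysis
(ICA). Before rs-fMRI can be trusted in this role, its maps must be scored
quantitatively against tb-fMRI and against the intraoperative gold
standard, electro-cortical stimulation (ECS).

`motormap` implements that scoring pipeline end to end:

1. **Mapping.** Block-design GLM t-maps (canonical double-gamma HRF,
   per-run OLS without autocorrelation correction); SBA t-maps from
   anatomical (aROI) or functional (fROI) seeds; spatial ICA with automated
   selection of the sensorimotor component.
2. **Thresholding.** AMPLE (activation mapping as percentage of local
   excitation): the threshold is 50 % of the highest statistic in the motor
   cortex ipsilateral to the lesion; a fixed-value policy is also
   available.
3. **Concordance.** Overlap sensitivity and specificity
   (`alpha = V_overlap / V_tb`, `beta = V_overlap / V_rs`, counted within a
   dilated motor-cortex evaluation mask), t-weighted centre-of-mass (CoM)
   distances, lesion-CoM distances, and distances from ECS sites to the
   activation border with <7 / <10 mm match rates.
4. **Aggregation.** Group mean/SD summary rows in the conventions of the
   study tables this pipeline operationalizes (packaged as per-case
   fixtures; see below).

Because no patient data can ship with the package, a synthetic BOLD
phantom with known ground truth exercises every stage, and every metric is
additionally checked against brute-force oracles in the test suite.

## The resting-state preprocessing chain

`preprocess_rest()` applies, in fixed order: confound regression (when
nuisance time courses are supplied), per-voxel polynomial detrending
(order 3 default), a zero-phase low-pass filter (0.1 Hz default), global
signal regression, and isotropic Gaussian smoothing (8 mm FWHM default).
The order is part of the contract: global signal regression operates on the
*residual* global fluctuation left after detrending and filtering, and
smoothing is applied exactly once to statistic-relevant data (the series,
before mapping).

Numerical choices worth knowing:

* **Low-pass filter.** Only the cutoff is part of the method definition,
  not a filter family. We use frequency-domain apodization with a
  raised-cosine roll-off of 0.02 Hz centred on the cutoff. Being applied
  symmetrically in the DFT domain it has exactly zero phase shift, which
  matters because phase shifts would displace centre-of-mass and overlap
  comparisons. The contract is stated on pass/stop behaviour (gain >= 0.95
  at half the cutoff, <= 0.05 at twice it) and tested that way.
* **Detrending basis.** Orthonormal polynomials (`stats::poly`), so the fit
  is numerically stable and basis-invariant.
* **Smoothing.** Separable convolution with sigma = FWHM / (2 sqrt(2 ln 2))
  per axis in mm, kernels truncated at 4 sigma, zero-padded edges. Masks
  are applied after smoothing, never before.
* **tSNR.** Mean over temporal SD per voxel, averaged over a white-matter
  mask; zero-variance voxels are excluded with a warning.

## Mapping methods and their parameters

* **HRF**: double gamma, response peak 6 s, undershoot peak 16 s,
  undershoot ratio 1/6, sampled at the TR and normalized to unit peak.
* **GLM / SBA**: per-voxel OLS with intercept (plus optional confounds);
  the map value is the t statistic of the regressor, `dof = t - p`.
  Perfect fits are capped at |t| = 1e8. t-maps are scale-free, which the
  tests assert.
* **Seed ROIs**: the hand aROI intersects a gyrus mask with a 10 x 2 mm
  axial slab centred on the hand-knob z coordinate. The slab is the
  symmetric half-open interval `[z - 10, z + 10)` mm: the source rule
  ("the 10 2-mm slices around it") does not say whether the knob slice
  counts symmetrically, so we fix the symmetric reading and record it in
  the output metadata. The foot aROI is the whole paracentral lobule; the
  mouth aROI is the ventral precentral gyrus between the Sylvian-fissure
  level and the inferior limit of the hand knob (half-open in z). The fROI
  is a 6 mm-radius sphere (voxel centres within the radius) around the
  activation peak of the non-diseased limb; peak ties break to the lowest
  linear index and are logged.
* **Spatial ICA**: PCA whitening of the in-brain spatial data to a fixed
  20 components, then fixed-point negentropy maximization (logcosh
  contrast, symmetric decorrelation, tolerance 1e-6, at most 500
  iterations, seed exposed). Component sign is fixed by non-negative
  spatial skewness; maps are z-scored over the brain mask. The
  sensorimotor component is selected automatically as the component with
  the highest fraction of supra-threshold (z >= 2 by default) voxels
  inside the pre/postcentral mask — a deterministic stand-in for the
  expert-consensus choice used clinically, and flagged as such in the
  selection report. The z = 2 criterion is a package choice; the
  underlying clinical procedure has no published numeric threshold.
* **Dilation semantics**: "dilated by k voxels" is read as k iterations of
  6-connected binary dilation (a city-block ball), recorded in the mask's
  `dilation_voxels` provenance field, and checked against a distance-
  transform oracle. Evaluation masks use 2 iterations for the
  pre/postcentral gyri and 6 for the paracentral lobule.

## Concordance metrics

* **AMPLE** uses `>=` for supra-threshold membership, so the peak itself is
  always included; the peak search is restricted to the motor cortex
  ipsilateral to the lesion, but the thresholded set is computed over the
  whole map. A non-positive in-mask maximum is an error ("no excitable
  peak").
* **alpha/beta** are undefined when either masked supra-threshold set is
  empty; this raises an error mirroring the "- -" cells of the source
  tables rather than silently producing 0/0. Whether the evaluation mask
  should be bilateral or ipsilateral is not fixed by the method
  description; the pipeline uses the bilateral motor mask by default and
  records the choice in the output (`mask_label`).
* **CoM** pools *all* supra-threshold voxels inside the anatomical mask
  (no cluster pre-selection), weighting by t-scores; lesion CoMs are
  unweighted centroids. All distances are Euclidean in world mm via the
  affine; voxel indices never appear in reports.
* **Lesion distance** is measured to the lesion CoM (the procedural
  definition); a border-distance variant would be a straightforward
  extension but the CoM reading is the one implemented, since the
  methodological definition names the CoM of the segmented lesion.
* **ECS scoring**: sites outside the cortex mask are projected to the
  nearest cortex voxel centre (ties to the lowest linear index, logged);
  the distance to the activation border is 0 when the projected site's
  containing voxel is supra-threshold, else the distance to the nearest
  supra-threshold voxel centre. Match rates use strict `<` at 7 and 10 mm.
* **Aggregation**: sample SD (n-1), with single-value groups reported as
  SD 0 and flagged; missing cells are excluded, never imputed; the two
  missing-data markers ("-" = map unavailable, "--" = no reference task
  map) are kept distinct throughout.

## The packaged per-case tables

The per-case overlap, CoM-distance and ECS-distance values of the source
study are shipped as checksummed TSV fixtures and are *inputs* to the
aggregation layer, not recomputation targets: the underlying patient data
do not exist publicly, so only the summary rows (means, SDs, proportions)
are recomputed by the package. One caveat is inherent: the packaged cells
are printed at 2 decimals (overlap) or 1 decimal (mm), while the original
summary rows were averaged from unrounded values. Re-aggregating rounded
cells can therefore differ from a printed summary by up to one unit in the
last printed digit (e.g. a grand mean specificity of 0.5156 against a
printed 0.51), and the acceptance tests compare at exactly that tolerance.
Proportions (match rates) are exact.

## The synthetic phantom

`phantom_spec()` describes a 36 x 36 x 30 grid of 2.5 mm isotropic voxels
(RAS+, origin at the grid centre) with parametric regions: parasagittal
pre- and postcentral slabs with a spherical hand-knob bump protruding into
the central-sulcus gap, medial paracentral boxes, a ventral mouth strip, an
ellipsoidal lesion adjacent to the right central region, an ellipsoidal
white-matter core, and a brain mask defined as a central ellipsoid unioned
with every structure (so all signal-carrying voxels are inside the brain —
important because nuisance terms are added to brain voxels only, and a
cortex partially outside the brain mask would have spatially nonuniform
residual variance and a biased AMPLE peak). Regions are parametric rather
than atlas-derived so no download is needed; the knob bump specifically
exercises the slice-based hand-ROI rule.

Simulated signals, all on a baseline of 100:

* **Task runs**: 18 blocks of 8 volumes at TR 3 s (six repetitions of
  rest / left / right, i.e. 12 active blocks — 6 per side — and 6 rest
  blocks; 144 volumes, close to the 140-volume clinical protocol the
  design emulates but chosen to tile the run exactly). Activated voxels
  carry the boxcar-convolved HRF scaled to `task_effect` percent (left
  blocks drive the right-hemisphere mask and vice versa).
* **Rest runs**: 200 volumes at TR 2.8 s. Network voxels share one
  band-limited source: white noise brick-wall filtered below 0.1 Hz and
  z-scored (less than 1 % of its spectral energy above 0.1 Hz by
  construction), scaled to `network_amplitude` percent. The network region
  is the dorsal sensorimotor strip (the gyri within the hand-area z
  window), a compact ~10 % of the brain: with z-scored ICA maps the
  plateau value of a component scales like sqrt((1-p)/p) in the network
  fraction p, and a network occupying a third of the brain would sit below
  the z = 2 selection threshold. The compact strip is both more realistic
  and the reason automated component selection is reliable.
* **Nuisance**: per-voxel random polynomial drift (orders 1-3, SDs
  `drift_coeffs`), one shared global fluctuation, and i.i.d. Gaussian
  noise. One RNG stream per operation (seeded from `spec$seed` plus an
  operation-specific offset) keeps every output bit-reproducible and
  insensitive to adding new operations.

Default amplitudes (2 % task effect, 2 % network amplitude, noise SD 0.5,
drift SDs 0.3/0.2/0.1, global 0.3 %) have no counterpart in the source
protocol, which reports no patient effect sizes; they were chosen once for
testability at a plausible operating point — the resulting white-matter
tSNR of ~150 sits inside the 160 +/- 11 / 194 +/- 2 range reported for the
two scanners — and are deliberately benign: recovery margins (Dice ~0.85
for the task map, ~0.84-0.90 for SBA, ~0.7-0.85 for ICA across seeds) test
pipeline correctness, not detection power at clinical noise levels.

What the phantom does **not** emulate: head motion, slice timing,
physiological (cardiac/respiratory) noise, field-strength differences,
temporal autocorrelation, realistic cortical folding, or operator-chosen
thresholds. Passing recovery tests therefore demonstrates that the
pipeline's stages are implemented correctly and compose correctly — not
that the method would achieve these Dice values on patient data.

## End-to-end run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(include_self_check = TRUE)
rec <- run_pipeline(cfg)
rec$overlap   # alpha/beta per method, 'self' row must be exactly 1/1
rec$dice      # recovery vs planted truth
rec$ecs       # site distances per method + offset-recovery column
```

The pipeline treats one phantom as one case: it simulates task and rest
runs, preprocesses, builds all maps, applies AMPLE (peak search in the
right-hemisphere motor mask, since the phantom lesion is right-sided and
the diseased hemisoma is the left one), scores overlap within the dilated
bilateral motor mask, computes CoM and lesion distances, and scores
synthetic ECS sites placed at a known offset from the activation surface.
A stage failure marks that method unavailable (the "-" semantics of the
source tables) and the run continues. Reports are written as rounded TSV
plus full-precision JSON; two runs with the same seed produce
byte-identical JSON.

Problem sizes are chosen so the full suite (unit, property and end-to-end
tests) runs in well under two minutes on one CPU: the default phantom has
38 880 voxels, 200 rest volumes and 144 task volumes, and oracle checks
run on random 20^3 grids.

## Known limitations

* The automated ICA component selection is a stand-in for expert consensus
  and its z = 2 criterion is a package convention.
* Operator-dependent thresholding is out of scope by design; only AMPLE
  and fixed thresholds are implemented, so operator-threshold results can
  only be reproduced from the packaged per-case tables.
* Statistical comparison of methods (ANOVA, Bonferroni) is out of scope;
  the aggregation layer stops at summary tables.
* `alpha`/`beta` depend on the evaluation-mask choice (bilateral default);
  per-case mask volumes of the original patients are not recoverable, so
  per-case overlap values are fixtures, not recomputation targets.
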