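---
title: "Component-based evaluation of lesion segmentations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Component-based evaluation of lesion segmentations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionwise)
```

## Why component-based evaluation

Whole-volume overlap metrics hide clinically decisive failures. A brain-MRI
examination with one large tumour and thirty small white-matter
hyperintensities can score a Dice similarity coefficient above 0.85 while the
model misses every small lesion: the large component dominates the voxel
counts. lesionwise therefore evaluates a detection mask against its reference
ground truth (GT) twice:

1. **Whole abnormal volume**: voxelwise Dice
   $\mathrm{DSC} = \frac{2|A \cap B|}{|A| + |B|}$, sensitivity
   $\mathrm{TP}/(\mathrm{TP}+\mathrm{FN})$ and precision
   $\mathrm{TP}/(\mathrm{TP}+\mathrm{FP})$ per case, summarised over the
   cohort and stratified by case volume.
2. **Single components**: each connected component of the GT mask and of the
   detection mask is scored and classified on its own, so every individual
   lesion — however small — counts once.

### Per-component Dice and the category taxonomy

For a component $C$ on one side, the counterpart set $U$ is the union of all
opposite-side components sharing at least one voxel with $C$, and

$$\mathrm{DSC}(C) = \frac{2\,|C \cap U|}{|C| + |U|},$$

zero when nothing overlaps. Using the union of *overlapping* counterparts —
rather than the single best match or the entire opposite mask — lets one
detection blob legitimately credit several GT lesions it covers, while remote
components cannot inflate or dilute the score. No exclusivity is enforced:
GT and detection sides are classified independently by the same rule, which
is why the two sides' category counts need not be equal.

Components are classified with two thresholds, both inclusive at their lower
edge:

| category (GT side / detection side) | rule |
|---|---|
| Found GT / Good Detection | DSC ≥ 0.5 |
| Partially Found / Partially Good | 0.05 ≤ DSC < 0.5 |
| Missed GT (false negative) / Missed Detection (false positive) | DSC < 0.05 |

A Dice of exactly 0.5 is Found, exactly 0.05 Partially Found. A sweep over
thresholds 0.05–0.95 (step 0.05) shows how counts and component volume decay
as the bar is raised.

### Positional and intensity profiles

Each component's unweighted voxel centroid is expressed as a signed offset in
mm from the brain centre, defined as the centroid of the brain mask
(bounding-box centre available as a sensitivity check). Axes follow a fixed
convention — X toward the anatomical left, Y anterior, Z superior — and NIfTI
volumes carrying an orientation are reoriented to it on load, so signs are
interpretable across datasets. Half-brain concentration differences use
$100\,(N_+ - N_-)/(N_+ + N_-)$ per axis and category; components exactly on
the centre plane belong to neither half. The denominator is the category
total in both halves, not the smaller half; this choice is stated in the
output metadata since the two readings of "x% more on the left" differ.

The intensity difference (ID) of a component in one modality is its percent
deviation from the mean intensity of a healthy white-matter reference VOI:

$$\mathrm{ID} = 100 \cdot \frac{\bar{I}_{\mathrm{component}} - \bar{I}_{\mathrm{VOI}}}{\bar{I}_{\mathrm{VOI}}}\,\%.$$

IDs are computed on intensities already stretched to the 12-bit range
[0, 4095]. The order matters: ID is invariant under pure rescaling but not
under an affine map with offset, so stretching after computing IDs would
change them. The package computes IDs on whatever intensities it is given
and exposes `stretch_to_12bit()` for the normalisation step; a property test
pins this contract down.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `tau_found` | 0.5 | — | at least half the volume must match; the common lesion-detection bar |
| `tau_partial` | 0.05 | — | below this, overlap is negligible |
| `connectivity` | 26 | — | faces+edges+corners, the common 3D clinical convention; 6 available |
| `volume_group_edges` | 10, 100 | cm³ | case strata [0,10), [10,100], (100,∞); middle stratum closed on both edges for determinism |
| `sweep_thresholds` | 0.05–0.95 by 0.05 | — | the standard sweep grid |
| `bin_width_mm` | 10 | mm | matches the ±20/±40 mm granularity at which positional effects are discussed |
| `correlation` | pearson | — | GT-vs-detected volume; spearman available |

Metrics with a zero denominator (e.g. sensitivity on an empty GT) are
reported as `NA` and excluded from aggregates — never coerced to 0 or 1.
Quantiles interpolate linearly between order statistics. Rendered tables
round metrics to two decimals and percentages to one; machine-readable JSON
keeps full precision.

## The phantom generator

Real multi-pathology cohorts with expert ground truth are not
redistributable, so every statistic the package computes must be checkable
against a synthetic truth. `phantom_spec()` / `generate_bundle()` build one
case analytically:

* **Brain**: a sphere (default radius 75 mm) on a 72³ grid at 2.5 mm
  isotropic spacing. These sizes keep a 24-case cohort cheap (a case is
  ~0.4 M voxels) while leaving room for lesions up to 100 cm³.
* **Lesions**: axis-aligned ellipsoids with mild random anisotropy
  (semi-axis ratios U(0.75, 1.3), normalised to the target volume). Realised
  volume lands within a voxel shell of the target and the centroid within
  half a voxel.
* **Detections**: per lesion, either an identical copy, a *concentric
  resize* of the ellipsoid whose erosion offset is solved numerically so the
  nested-overlap Dice $2V_d/(V_d+V_g)$ equals the planned per-component
  Dice, an integer-voxel translation, or a drop (a planned Missed GT).
  The analytic resize was chosen over voxel-level morphology because it is
  exactly equivalent for these analytic shapes and gives direct, monotone
  Dice control. Spurious ellipsoids painted only into the detection mask
  become planned Missed Detections.
* **Modalities**: healthy tissue at a flat background level (default 1000),
  each component's voxels at `background × (1 + ID/100)` for its planned
  per-modality ID, then optional additive Gaussian noise (masks stay
  clean). Before noise, recovery of the planned ID is exact by
  construction — a property the tests assert.
* **VOI**: a sphere (default r = 10 mm, ~270 voxels) placed at the candidate
  grid point with maximal clearance from every component, guaranteeing the
  disjointness the ID definition requires.
* **Determinism**: a seed fixes everything; the same seed yields a
  bit-identical bundle.

`generate_cohort()` draws cases from `phantom_template()`: 2–6 lesions per
case with volumes log-uniform on 2×10³–10⁵ mm³, planned categories with
probabilities 0.49 / 0.27 / 0.24 (the proportions a multi-pathology
validation cohort reports), planned Dice U(0.6, 0.95) for Found and
U(0.15, 0.45) for Partially Found, per-modality ID draws of FLAIR U(10, 65),
T2 U(0, 70), T1ce U(−30, 20) percent, zero to two micro false positives
(100–500 mm³) per case, and noise at 2% of background. The planned-Dice
ranges deliberately keep ≥ 0.1 distance from the 0.5 and 0.05 category
boundaries so that voxelisation error (empirically below 0.04 for these
lesion sizes) cannot flip a planned category.

### What the phantoms do and do not show

Phantoms validate the *evaluation machinery*: component extraction,
matching, classification, positional and intensity bookkeeping, and
end-to-end determinism. They do not emulate MRI physics (no bias fields,
partial-volume effects, anatomy, or irregular lesion shapes), and the
erosion-based perturbation makes detections nested inside their lesions, so
whole-volume sensitivity runs low and precision high relative to a real
segmentation model. Passing phantom tests therefore demonstrates that the
framework measures what it claims to measure — not that any particular model
performs well on clinical data.

## Numerical choices and degenerate inputs

* Connected-component labels are deterministic: component *k* is the one
  whose first voxel comes *k*-th in column-major scan order. Labelling is
  checked against an independent brute-force flood fill on exhaustive and
  randomised small grids.
* Constant grids stretch to all-zero (there is no range to map).
* 2D inputs are rejected rather than promoted; the framework is 3D-only.
* Binary NIfTI masks are thresholded at 0.5 on load to tolerate
  interpolation residue.
* A component with no overlapping counterpart scores Dice 0, not `NA`.
* Empty volume strata are reported as empty rather than dropped silently;
  a single-case cohort reports its volume correlation as undefined.
* Problem sizes in the shipped tests: exhaustive 3×3 slice occupancies plus
  10⁴ sampled 3×3×3 grids (6-connectivity) and 200 random 6×6×6 grids
  (26-connectivity) for the labelling oracle; 24-case phantom cohorts for
  plan-recovery checks — together about two minutes on one CPU.

## Known limitations

* One healthy VOI per case; per-modality VOIs are not supported.
* No anatomical-atlas localisation: positions are offsets from the brain
  centre, not region labels.
* Instance matching is overlap-union based; Hungarian/panoptic assignment
  schemes are out of scope.
* The volume-strata averages weight each case equally by default; pooled
  voxel-count aggregation is available (`pooled_groups`) because the two
  conventions diverge for heterogeneous case sizes and the reporting
  convention in the field is often left unstated.
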