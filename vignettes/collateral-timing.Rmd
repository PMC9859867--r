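---
title: "Time-resolved collateral scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved collateral scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collateraltime)
```

## The problem

Collateral status in large-vessel-occlusion stroke is scored by comparing
contrast-enhanced vessel volume between the occluded and the healthy middle
cerebral artery (MCA) territory. On a single CT angiogram this collateral
ratio (CR) is a snapshot of a dynamic process: the occluded side fills
late, through pial collaterals, so the score depends on where in the
contrast passage the snapshot falls. This package analyses that time
dependency on dynamic CT perfusion (CTP) series — roughly 30 volumes at 2 s
intervals over about a minute — and places sparse multiphase CTA (mCTA)
acquisitions on the same time axis so their CRs can be interpreted by
acquisition phase.

## Per-frame collateral scoring

Each CTP frame is segmented by subtraction thresholding: a voxel is vessel
iff it lies in an MCA region mask and its enhancement over the unenhanced
baseline volume (the mean of the first two frames, before bolus arrival) is
at least `enhancement_threshold_hu` (default 50 HU, a conventional
angiographic enhancement cut-off at low tube voltage). The comparison is
inclusive (`>=`) so boundary behaviour is deterministic. This stand-in
segmentation is deliberately simple; the function boundary
(`segment_vessels()`) is the single point at which a learned vessel
segmentation could be substituted.

The CR is `100 * vol_occluded / vol_contralateral`. Frames whose
contralateral volume is zero (before arrival, after washout) carry `NA`
rather than 0 or infinity: a ratio with an empty denominator has no value,
and all curve consumers skip missing frames. The CR is reported unclamped
by default; automated CTA collateral scores are sometimes presented on a
bounded 0–150 scale, and cohort summaries here show venous-phase medians
well above 100, which a clamp would distort. A `cr_cap` option reproduces
the bounded variant where needed.

A timing-invariant score, `cr_mip`, applies the same scoring to the
voxelwise maximum-intensity projection over all frames. Because the MIP
captures every voxel at its individual peak, it bounds any single frame
from below and recovers late-filling collateral voxels that an
arterial-peak snapshot misses.

## Enhancement curves and the phase model

Arterial and venous enhancement are the median intensity of small spherical
ROIs (at the carotid top of the non-occluded side and the confluence of
sinuses). The median uses voxel-center inclusion and the lower-middle
convention on even counts, so it always returns an observed intensity and
is reproducible against a brute-force oracle. The ROI radius is not a
physiologically critical constant; 3 mm is the default where a region
specification does not state one (the phantom uses 4.5 mm so several voxel
centers fall inside at 3 mm voxels).

The arteriovenous (AV) enhancement ratio subtracts the density of
unenhanced blood (40 HU) from both values before dividing,
`(a - 40) / (v - 40)`. The ratio is undefined until venous density exceeds
40 HU, and a negative arterial excess is clamped to zero. Contrast arrival
is detected on the arterial curve as the first crossing of baseline + 10 HU
(linearly interpolated); the rule and its delta are package conventions —
arrival detection is not prescribed by the scoring definitions — and both
are parameters of `extraction_params()`. All AV-ratio analysis (peak
finding, equilibrium, alignment) is restricted to times at or after
arrival: with measurement noise the venous median can sit fractionally
above 40 HU before any contrast has arrived, and the near-zero denominator
produces arbitrarily large spurious ratios.

For phase classification the AV-ratio curve is normalized per subject:
equilibrium (ratio = 1) maps to 0 and the curve maximum to 1,
`(r - 1) / (r_peak - 1)`. The equilibrium time is the first downward
crossing of the raw ratio through 1 after the peak, linearly interpolated;
the normalization maximum is the global (post-arrival) ratio maximum, which
coincides with the pre-equilibrium maximum on well-formed curves. Phases on
the normalized curve:

| phase | definition |
|---|---|
| PRE | before arrival, or on the upslope below 0.2 |
| EA (early arterial) | upslope, 0.2 to 1.0 |
| PA (peak arterial) | downslope, 1.0 to 0.5 |
| EQ (equilibrium) | downslope, 0.5 to 0 |
| PV (early venous) | 0 down to the curve minimum |
| LV (late venous) | after the minimum, returning towards 0 |

Numerical conventions: "upslope/downslope" is operationalized as
before/after the ratio peak; boundary values belong to the later phase
(v = 0.5 after the peak is EQ, v = 0 is PV); the EQ/PV boundary is the
equilibrium *time*, so late samples where noise lifts the ratio
fractionally above 1 stay venous; if the acquisition ends before the
post-minimum return to 0, LV simply extends to the last valid sample, and
if it ends before any minimum, the minimum is the last sample. Ties in peak
finding go to the earliest frame.

## Aligning mCTA to the CTP time axis

An mCTA gives three AV ratios at known relative delays but an unknown
absolute position in the contrast passage. The alignment places the triplet
on the CTP AV-ratio curve by exhaustive grid search over the offset
(default step 0.1 s), minimizing the summed absolute ratio difference with
the CTP curve linearly interpolated between frames. Exhaustive search is
exact at grid resolution, trivially testable, and fast (a few hundred
candidates). Ties break to the earliest offset; a flat CTP curve triggers a
degenerate-alignment warning and returns the earliest offset; a manual
`offset_s` override replaces any interactive fallback. The objective uses
raw ratios; matching on the normalized curve is available as a sensitivity
option (`use_normalized`).

## Landmark CRs and the subject profile

Six landmark times are read from the curves — contralateral and occluded
volume peaks, arterial and venous enhancement peaks, AV-ratio peak, and the
equilibrium point — and the CR at each landmark is taken from the *nearest
acquired frame*: the CR is a ratio of segmented volumes and only exists at
frames, so interpolating it would manufacture data. Landmark peaks may
optionally be located on a centered moving average (`smoothing_window`,
default off for noise-free work and 3 frames in the cohort pipeline);
stored curves are never smoothed. Missing landmarks propagate as missing
CRs.

## Cohort statistics

Spearman correlations are Pearson correlations of average ranks with
two-sided p-values from the t approximation on n − 2 degrees of freedom.
Regressions of CR against covariates z-score both variables and report the
standardized slope with a t-based 95% CI — for simple regression this slope
equals the Pearson correlation, which the tests verify numerically to
1e-10. Association tables bounded by (−1, 1) without units are naturally
read as standardized coefficients, and the unstandardized variant is a
one-line change on the z-scoring. Missing CRs are deleted pairwise (each
correlation uses all complete pairs for that pair of variables); quartiles
use the linear-interpolation convention (R type 7), stated here because
IQRs depend on it.

## The synthetic phantom

No patient data ship with the package, so every stage is exercised on a
seeded contrast-enhancement phantom:

* **Geometry** — a brain ellipsoid on a 64×64×32 grid of 3 mm voxels with
  two tubular vessel trees constructed in the left hemisphere and mirrored
  voxel-for-voxel across the midsagittal plane, so perfect collaterals
  (`collateral_fraction = 1`, zero delay) are exactly symmetric and the CR
  oracle is exactly 100. MCA region masks are dilated bounding boxes
  clipped to each hemisphere (hence disjoint by construction).
* **Bolus kinetics** — the arterial ROI follows a gamma-variate
  (`t0 = 8 s`, shape 3, scale 1.5 s, peak 250 HU above the 40 HU blood
  baseline) plus a slow recirculation/steady-state component (20% of the
  arterial amplitude, 4 s on-ramp, 40 s decay) shared by artery and vein —
  after first pass both compartments converge to the same decaying blood
  pool, which is what drives the AV ratio back towards 1 and creates the
  late-venous phase. The venous ROI adds a first-pass component delayed by
  `venous_delay_s` with the same shape-scale product (so the venous peak
  lags the arterial peak by exactly the configured delay) but faster
  washout. A venous curve that were a pure shifted copy of the arterial one
  would make the ratio monotone after its peak and the late-venous phase
  would never exist.
* **Vessel filling** — each hemisphere's tree has an arterial-like and a
  venous-like compartment with per-voxel amplitude weights (1.5 down to
  0.15 along the tree) and onset dispersion (0–2 s arterial, 0–3 s venous).
  The spread makes enhanced-vessel volume a smooth function of time and
  keeps the CR defined out to ~40 s, where the second mCTA delay falls.
  Occluded-side vessels follow the same curves scaled by
  `collateral_fraction` and shifted by `collateral_delay_s` (default 0.6
  and 3 s — a moderately impaired collateral bed).
* **Noise and sampling** — i.i.d. Gaussian voxel noise (default 5 HU, a
  smoothed-reconstruction level) under a mandatory seed; 2 s frames over
  58 s (30 volumes); mCTA volumes are evaluated from the continuous
  noise-free model at `offset, offset + d1, offset + d1 + d2`.
* **Cohort** — collateral fractions uniform on [0.05, 1]; ASPECTS-like
  covariate `round(4 + 6f + N(0,1))` clipped to 0–10 and NIHSS-like
  `round(25 − 18f + N(0,3))` clipped to 0–42, linear-plus-noise links with
  slopes spanning clinically plausible ranges so the association stage has
  known recoverable structure; mCTA offsets at arrival + N(8, 1) s with
  delays near 8 s, emulating bolus tracking.

What the phantom does **not** emulate: patient motion (inputs are assumed
registered), beam hardening, realistic vascular anatomy, partial-volume
effects, inter-side tissue asymmetry, or visual score reading. Passing
tests therefore demonstrate the correctness and determinism of the
measurement and alignment machinery under controlled kinetics — not
clinical performance on real CTP data, where segmentation quality and
motion dominate.

## Problem sizes and determinism

The test suite runs the symmetric-phantom oracle at the full default grid;
property tests (alignment recovery over 50 subjects, phase classification
against a dense 0.01 s brute-force labeler over 100 curves, alignment noise
trials at sd 0.05 over 200 draws) use a 32×32×16 grid whose ROI curves are
identical to the full-size phantom; the cohort checks run 58 subjects at
the full grid. All randomness flows from explicit seeds; `run_pipeline()`
embeds the seed and a configuration hash in every output file name, and a
rerun with the same configuration is byte-identical.

## Conventions and limitations

* Voxel indices are 1-based throughout (R convention); JSON sidecars state
  `index_base: 1`. Times are seconds from the first CTP frame; frame 1 is
  t = 0.
* Volumes travel as NIfTI with a JSON sidecar for per-frame times (NIfTI
  has no per-frame acquisition-time field); DICOM is out of scope.
* The alignment assumes the CTP AV curve covers the mCTA window; mCTA
  acquired entirely outside the CTP acquisition cannot be aligned and
  raises an error rather than extrapolating.
* With very low collateral fractions the occluded side may never cross the
  segmentation threshold at early landmarks; the resulting CRs of 0 (or
  missing CRs where a whole curve is empty) are faithful outputs, not
  failures.
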