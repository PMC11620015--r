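---
title: "Grid-based choriocapillaris flow-deficit quantification: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based choriocapillaris flow-deficit quantification: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccfdgrid)
```

## The measurement problem

The choriocapillaris (CC) is the capillary monolayer directly beneath
Bruch's membrane (BM) that supplies the retinal pigment epithelium and
photoreceptors. On en-face OCT angiography, regions where CC flow falls
below the detection threshold appear as *flow deficits* (FDs), and the
fraction of analysable area they occupy — the CCFD% — is a widely used
marker of CC impairment in ageing and age-related macular degeneration
(AMD). Comparing CCFD% across visits of the same eye is harder than it
sounds: lesions such as hyperreflective foci (HRF), calcified drusen and
hypertransmission defects corrupt the CC signal and must be masked out;
drusen attenuate the OCT beam and create spurious deficits; repeat scans
are never perfectly aligned; and any longitudinal claim needs a
repeatability bound that separates true change from test–retest noise.

`ccfdgrid` implements the complete measurement chain: per-scan CCFD
quantification (slab projection, attenuation compensation, fuzzy C-means
thresholding, size filtering, exclusion masking), cross-scan registration
with an integrated mask, CCFD% measurement in fovea-centered circles and
a 74-pixel box grid, the companion repeatability statistics (nested
variance components, ICC, MDC95, Tukey-adjusted group contrasts), and an
MDC95-based change test — together with a synthetic-eye generator that
provides ground truth for every stage.

## Per-scan quantification

**Slab projection.** The CC en-face pair is projected from the volume as
a 16-µm slab starting 4 µm below BM; the sub-RPE slab (64–400 µm below
BM) supports lesion identification. Depths convert to voxel indices via
the axial spacing; a voxel at depth `d` below BM is in the slab when
`d ∈ [offset, offset + thickness)`. The projection statistic is the mean
by default (`max` is available): the mean preserves the linear relation
between shared attenuation and slab intensity that the compensation step
relies on, and nothing in the downstream chain depends on the choice.

**Compensation.** Drusen and RPE abnormalities attenuate both the CC
flow and CC structure images multiplicatively. The default `divide` mode
computes `flow / max(smooth(structure), floor)` and rescales so the
median over unmasked pixels is unchanged; under a shared multiplicative
attenuation field this removes the artifact exactly, which makes the
step testable against ground truth. A `complement` mode
(`flow × (max − smooth(structure))`) is provided as the classical
"inverted structure" variant. Smoothing is Gaussian with σ = 2 px by
default — wide enough to suppress pixel noise in the divisor, narrow
enough to track drusen borders. The floor is the 5th percentile of the
smoothed structure: dividing by values below the low tail of the
structure distribution amplifies noise more than it corrects signal. A
consequence worth knowing: a shadowed region can only be compensated if
intensities of its kind carry real mass in the structure histogram —
isolated attenuation covering far less than the floor quantile is
floored, not divided out. This is intentional (it is what "avoid noise
amplification" means operationally) and shapes the synthetic fixtures
below.

**Thresholding.** The global threshold is a two-cluster fuzzy C-means
(fuzzifier m = 2) on the unmasked intensity distribution, accelerated on
a 256-bin histogram, with centers initialised at the 10th/90th
percentiles, tolerance 1e-6 and at most 300 iterations; the threshold is
the midpoint of the converged centers. All choices exist to make the
step deterministic and checkable against an unbinned implementation;
the histogram acceleration changes the threshold by well under the
2-intensity-unit tolerance the tests enforce. Pixels strictly below the
threshold are deficits; masked pixels never are.

**Size filtering.** Deficits smaller than 24 µm in greatest linear
dimension (GLD) are removed: they are indistinguishable from speckle
noise and physiological intercapillary voids at this scan scale. A
component (8-connectivity) has
`GLD = max pairwise pixel-centre distance × spacing + spacing`, so an
isolated pixel at 12-µm spacing has GLD 12 µm (removed) and two adjacent
pixels reach exactly 24 µm (kept). Adding one spacing makes a single
pixel's GLD equal its physical footprint and keeps the rule exactly
reproducible by pairwise enumeration, which the test suite does.

**Vessel projections and masks.** Large retinal vessels project onto the
CC slab; they are segmented on the retinal-vasculature en-face image by
a between-class-variance (Otsu) threshold plus a 1-px disc dilation, and
excluded from both numerator and denominator — the same semantics as the
lesion masks, which are inputs (HRF/calcified-drusen/hyperTD detection
is out of scope). A user-supplied vessel mask overrides the derivation.
The fixed stage order is: merge lesion masks → compensate → add vessel
mask → threshold → binarize → size-filter.

## Registration, integrated mask, ROIs

Repeat scans are registered on their retinal-vasculature images to the
first scan (the baseline). Translation is estimated at integer-pixel
resolution by an FFT correlation-peak search; rotation is available by
exhaustive search (±5° in 0.25° steps) but off by default — same-day
repeat scans are rotationally stable, and integer translations keep
binary maps exact under nearest-neighbour resampling. The registration
score is the Pearson correlation on the overlap; scores below a
configurable floor raise an error rather than returning a bad alignment.

The *integrated mask* is the union of every scan's registered combined
mask plus everything outside the common overlap, applied identically to
every scan, so only areas with meaningful CC measurement in all scans
are compared.

ROIs are 3-mm and 5-mm fovea-centered circles (pixel centres within the
radius; clipped with a warning if the scan is too small) and a
target-centered grid of 74 × 74-px boxes (~0.9 mm a side at 12-µm
spacing) propagated outward on the box lattice. A box is retained only
when complete — fully inside the registered overlap; lesion masking is
handled by the valid-pixel denominator, not by dropping boxes. With an
even box size no box is symmetric about a pixel; the target box is
anchored at `centre − floor(size/2)`, a documented deterministic choice.
On a fully overlapping 500-px scan the fovea-centered grid has 25 boxes
(19.71 mm², nearly the 5-mm circle's 19.63 mm²); the best-offset packing
reaches 36. CCFD% is `100 × |FD ∩ valid| / |valid|`; the grid total
pools pixels across boxes (it is one region, not a mean of box
percentages), and a fully masked ROI yields `NA`, never a silent 0%.

## Repeatability statistics

The unconditional variance-components model has nested random
intercepts (patients, eyes within patients, boxes within eyes, as
applicable) with the repeat-to-repeat residual. Balanced tables are
fitted by expected-mean-squares method of moments (closed form);
unbalanced tables by REML, implemented directly as a profiled likelihood
over variance ratios optimised block-wise by top-level unit (tolerance
1e-8, components clamped at zero). The model family is small and fixed,
so a direct implementation keeps the statistic transparent and
testable; the test suite cross-checks it against an independent
general-purpose mixed-model fit.

* **ICC** = (total − residual) / total variance, clipped to [0, 1].
* **MDC95** = √2 × 1.96 × residual SD — the smallest between-visit
  change outside 95% test–retest variability. The √2 reflects that a
  change is a difference of two noisy measurements.
* **ICC confidence intervals** come from a parametric bootstrap:
  simulate tables from the fitted normal components under the same
  design, refit, take percentile bounds. The default is 1,000 samples
  (a practical default for interactive use; publication-grade runs can
  request 100,000 via `n_boot`). Coverage calibration (93–97% at
  nominal 95%) is verified by simulation in the test suite.
* **Group contrasts** add a group fixed effect and compare all pairs
  with Tukey's studentized-range adjustment. The range degrees of
  freedom are `n_eyes − n_groups`, a stated convention (not asserted as
  the only possible one); for balanced one-level designs the GLS fit
  reduces exactly to a one-way analysis of per-eye means, which is used
  as a closed form.
* **Change calls**: a box change is significant when |follow-up −
  baseline| *strictly exceeds* the MDC95 reference ("exceeded", not
  "reached"). The box containing the lesion of interest is the target;
  remaining boxes are internal controls.

Null CCFD% rows (fully masked ROIs) are dropped with a message before
fitting.

## The synthetic-eye generator

No public scans exist for this protocol, so the generator is the
package's source of controlled truth. It emulates, on the standard
500-px/12-µm raster:

* **FD texture** — thresholded correlated Gaussian noise with a 30-µm
  correlation length (the CC intercapillary scale), thresholded at the
  exact target deficit fraction (default 0.08, the healthy-macula
  CCFD% scale). This is a stand-in for real angiographic texture: it
  produces the right size distribution for the 24-µm filter and the
  right bimodal intensity structure for the threshold, but it is not a
  vascular growth model.
* **Shared attenuation** — drusen multiply both flow and structure by a
  smooth-edged factor (default 0.5 for the resolving druse). This is
  exactly the assumption under which divide-mode compensation is exact,
  stated openly: the compensation tests validate the implementation
  under its own model, not the biophysics of OCT shadowing.
* **Noise and repeats** — additive acquisition noise (SD 8 on a mean
  flow of 120) plus per-repeat noise (SD 6) and random integer-pixel
  misalignment (±6 px). The deficit contrast is 0.5: at high contrast
  (0.7) repeat scans give essentially identical CCFD% — residual
  variance collapses to zero, unlike any real scanner — while below
  ~0.4 the compensation's noise amplification inside shadowed regions
  (the generator's noise is additive after attenuation) inflates
  compensated CCFD% there, and near 0.35 the global threshold becomes
  unstable between repeats. 0.5 gives nonzero, stable test–retest
  variability and recoverable shadows; this was fixed once when the
  generator was designed.
* **Vessel tree** — a recursive branching rendering that exists purely
  to give registration realistic landmarks.
* **Drusen-resolution pairs** — the follow-up removes one druse's
  attenuation while the true FD field is unchanged ("resolution without
  anatomic sequelae"). The default fixture is multifocal: one resolving
  druse plus eleven persistent drusen (~7% of the scan attenuated).
  Multifocal drusen are the typical intermediate-AMD picture, and the
  persistence matters quantitatively: with a single small druse the
  5th-percentile compensation floor sits *above* the druse's attenuated
  structure level and the division never engages (see the compensation
  section). The fixture therefore exercises the mechanism under the
  conditions where it is defined to act.

What passing tests on this generator do **not** show: robustness to OCT
speckle statistics, segmentation error of BM, axial-length scale
distortion, eye-motion artifacts within B-scans, or non-multiplicative
shadowing. Those require real scans.

## Numerical choices and degenerate inputs

* Coordinates are `(row, col)`, 0-based, pixel centres at integer
  coordinates; one isotropic lateral spacing (anisotropic input is
  rejected at read time).
* FCM on fewer than two distinct unmasked intensities, an all-zero
  structure image, or an empty mask list where one is required all
  raise structured errors naming the problem.
* Connected-component labeling is 8-connected by vectorised min-label
  propagation (deterministic; converges in at most the longest
  within-component path).
* Bilinear resampling is used for intensity rasters, nearest-neighbour
  for binary rasters; validity masks track which target pixels mapped
  from inside the source, with the closed-form overlap count
  `(H−|dy|)(W−|dx|)` for pure translations used as a test oracle.
* Negative method-of-moments variance estimates are clamped to zero
  with a warning; REML clamps at the boundary of the ratio search.
* Bootstrap refit failures are dropped and counted; more than 5%
  failures raises a warning in the result.

## Problem sizes used in the test suite

Unit tests run on 60–250-px rasters; the end-to-end compensation
validation runs the full default 500-px fixture. The statistical
recovery suites use 30 eyes × 3 repeats with 500 simulation replicates
for unbiasedness and 200 replicates × 1,000 bootstrap samples for
interval coverage — sizes at which Monte-Carlo error is comfortably
inside the asserted tolerances.

## Known limitations

* Masks are inputs: no HRF/calcified-drusen/hyperTD detection, no BM
  segmentation from B-scans.
* Registration is rigid (translation, optional small rotation); no
  affine or deformable model, no axial-length lateral-scale correction.
* The mixed-model layer supports exactly the nested random-intercept
  family with one optional fixed factor — it is not general-purpose
  mixed-model software.
* Boxes are unweighted in the variance-component fits; a valid-pixel
  weighting is exposed as a future config option but the default
  follows the unweighted convention.
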