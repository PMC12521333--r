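---
title: "Quantifying regional lung aeration on neonatal chest radiographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying regional lung aeration on neonatal chest radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cxraeration)
```

## The measurement problem

Respiratory distress syndrome (RDS) in extremely preterm infants presents
radiographically as poorly inflated lungs, and surfactant replacement may
distribute unevenly, producing focal over-expansion next to atelectasis.
`cxraeration` quantifies this on ordinary frontal chest radiographs (CXR):
brighter (denser) lung tissue means less aeration, darker means more. Two
focal metrics are measured in each of twelve intercostal-segment regions
of interest (ROIs; sides left/right, intercostal spaces 2 apical to 7
basal):

* **MPI** — mean pixel intensity of the ROI, an inverse index of focal
  aeration;
* **FHPI** — the standard deviation of the same pixels, an index of focal
  heterogeneity of aeration.

From the twelve segment values per image the package derives per-lung
summaries (mean and SD of segment MPIs and FHPIs: STDV-MPI, STDV-FHPI as
between-segment heterogeneity indices), group-level per-segment means, and
apico-basal gradient fits (Pearson r and OLS line of segment means against
the space index).

Raw radiographs are not comparable across patients: exposure differs per
image, and so does the imaged scale. Both are removed before measurement.

## Normalization model

**Intensity.** For each image the brightest pixel inside an annotated
liver polygon serves as a per-image reference (the liver is the brightest
soft-tissue structure reliably present on neonatal CXRs). Every pixel `p`
is mapped to `p * target_level / reference`, a purely multiplicative
rescaling, so any per-image exposure gain cancels exactly. The common
`target_level` defaults to 255; the choice is arbitrary (it is a unit
convention) and is recorded in the provenance output. Values are *not*
clipped or re-quantized: lung pixels brighter than the liver reference
(possible with bone overlap) keep values above the target, because
clipping would bias MPI downward.

A two-point (air/liver) affine normalization was considered and rejected
as the default: the reference procedure is anchored to a single liver
point, and an offset term would change the meaning of MPI differences
between images. The multiplicative model is the default and the only one
used in the tests.

**Scale.** Each image carries a scale-bar annotation (two endpoints and a
physical length, normally 10 mm). The image is rescaled by
`factor = mm * 5 / endpoint_distance_px`, so that all images end up at
5 px/mm (a 10 mm bar spans 50 px). Resampling is bilinear — the common
default of ROI tooling; MPI is mildly smoothing-sensitive, so the
interpolation choice is logged in the provenance record. The resampled
image is centered on a canonical 2075 x 1170 px canvas (padding 0).
Centered rather than corner-anchored placement is a presentation choice
only: MPI and FHPI are exactly translation invariant, which the test
suite checks.

Coordinates are 0-based with origin at the top-left, x = column,
y = row, and pixel (r, c) has its center at (x = c, y = r). ROI
rasterization keeps exactly the pixels whose centers fall inside the
polygon (even-odd rule, boundary centers included); this is verified
against an independent winding-number oracle on random simple polygons.

**Numerical behaviour worth knowing.** Normalization is idempotent and
gain-invariant to floating precision. After bilinear resampling the liver
maximum may dip slightly below the target (interpolation can only lower a
regional maximum); the pipeline pins it within 0.5 intensity units, which
is far below between-segment contrasts. FHPI uses the sample SD (n - 1),
matching the StdDev convention of common ROI tools; at typical ROI sizes
(thousands of pixels) the difference from the population SD is below
0.1%. Degenerate inputs (empty liver polygon, zero reference, coincident
scale-bar endpoints, missing ROIs, self-degenerate polygons) raise errors
naming the offending annotation rather than propagating NaNs.

## What the phantom generator emulates

The synthetic module generates radiograph phantoms with known ground
truth so every stage of the analysis can be validated by recovery:

* two vertically elongated elliptical lung fields on a darker thoracic
  background (no ribs: the ROIs of the measurement protocol avoid
  non-lung structures, so phantoms need none);
* a linear apico-basal MPI gradient per side,
  `mean(side, k) = base_side + slope_side * k` for space `k` in 2..7. The
  defaults place the right lung at `-1.99x + 117.79` and the left at
  `-1.75x + 123.71`, i.e. basal segments are more aerated and the left
  lung is denser than the right — the configuration the analysis is
  designed to detect;
* per-segment Gaussian speckle whose SD is the FHPI ground truth
  (default 8 intensity units). Noise is truncated at 0 and at the
  bit-depth ceiling; the defaults keep segment means more than 5 SD from
  both bounds, so the truncation bias is negligible (a warning is issued
  if a specification violates this margin);
* a constant liver plateau at 255 — strictly the global pre-gain maximum,
  enforced at construction, because the normalization reference would
  otherwise be wrong. Since the analysis target level is also 255, the
  phantom's ground truth is expressed directly on the post-normalization
  intensity scale, and the truth is by construction independent of the
  exposure gain;
* a drawn scale bar (10 mm; drawn length configurable, 50 px by default)
  and a per-image exposure gain multiplying every pixel, which the
  intensity normalization must cancel end to end;
* segment ROIs as equal-height horizontal bands inscribed in each lung
  ellipse over its central 88% vertical extent, apical band = space 2 —
  generated programmatically because ROI placement in practice is manual.

Cohorts add between-patient structure: a per-patient intensity shift
common to both lungs (SD 10 units), a log-normal exposure gain (SD 0.15),
an optional group offset making the pre-surfactant group more aerated
(-10 units), and a 7/52 probability that a surfactant-treated patient's
right-7 segment is flagged `liver_overlap` (poorly inflated basal lung
over the liver); flagged segments are still measured but marked excluded,
so exclusion accounting stays auditable. Group sizes default to 52
surfactant-treated and 8 pre-surfactant patients, one analyzed radiograph
per patient. Day-1 mean airway pressure follows
`MAP = alpha + beta * MPI + eps`, with `beta = 0.2` cmH2O per intensity
unit and the residual SD derived so the population MPI-MAP correlation is
0.48; days 3 and 7 drift independently of MPI. FiO2 is uniform on
[0.25, 0.50], tidal volume has day means (5.0, 4.3, 5.8) mL/kg, and the
respiratory severity score is MAP x FiO2. A radiological grade 1-4 is a
monotone step function of patient mean MPI (cut points 100/110/120) with
10% single-step label noise. Between-patient spreads are not published
per segment for any real cohort; these values were chosen once as
clinically plausible and testable, not fitted.

What the phantoms deliberately do **not** model: anatomy (ribs,
mediastinum, catheters), spatially correlated texture, scatter, or
detector noise. Passing recovery tests therefore demonstrates that the
*computational pipeline* is unbiased and correctly plumbed under the
stated statistical structure — not that the metrics are clinically valid
on real radiographs, which requires patient data.

## Statistical battery

Two-sided p values throughout. Welch's heteroscedastic t (via
`stats::t.test`), Fisher's exact test for 2x2 tables (summed-probabilities
two-sided rule, cross-checked against full hypergeometric enumeration),
Pearson correlation with the t-based p on n - 2 df, one-way
repeated-measures ANOVA (`stats::aov` with an `Error(block)` stratum;
the SS partition is returned and the k = 2 case equals the squared paired
t), and Bonferroni adjustment `min(1, m p)` for post hoc families.

The Friedman test is implemented in the package because the base-R
version applies no tie correction: mid-ranks within blocks and the
tie-corrected statistic
`chi2 = (k - 1) sum_j (R_j - n(k+1)/2)^2 / (A - C)` with
`A = sum r_ij^2`, `C = n k (k+1)^2 / 4`; when every block is entirely
tied the statistic is 0 by convention. In tie-free data this equals the
base-R statistic exactly (tested).

Conover's all-pairs post hoc after Friedman uses
`t = |R_i - R_j| / sqrt(2 n (A - B) / ((n-1)(k-1)))` with
`B = sum R_j^2 / n`, referred to the t distribution on (n-1)(k-1) df.
This SE is identical to the least-significant-difference SE of a two-way
ANOVA on the within-block ranks. When rankings are perfectly consistent
across blocks the residual rank variance is zero; tied pairs then report
p = 1 and separated pairs p = 0. The implementation is checked against a
studentized within-block permutation enumeration (all k!^n orderings).
That agreement is within 0.03 for well-separated treatments at n = 5,
k = 3; for moderate effects the permutation distribution is too coarse
(7776 atoms) for any continuous approximation to track it more closely,
which is a property of the small-sample design, not of the
implementation.

The default report reproduces the study-style comparison set (group and
side contrasts of mean MPI, the right-7 vs left-7 FHPI contrast,
MPI-covariate correlations, and day-1/3/7 tidal-volume comparisons by
both the parametric and the rank-based repeated-measures route). No
multiplicity adjustment is applied across these distinct hypotheses;
adjustment is applied only within the post hoc families.

## Problem sizes used in validation

The packaged validation suite exercises: gain invariance at exposure
gains 0.5/1/2; scale-bar pinning for bars drawn 40-300 px; a 60-image
cohort yielding 720 segment records on the 2075 x 1170 canvas; exact
slope recovery on noiseless cohorts and +/- 0.3 slope recovery over 200
replicate cohorts of 20 patients per group at speckle SD 8 (run on a
reduced phantom geometry and placement canvas — placement and canvas size
do not enter MPI/FHPI); FHPI recovery at speckle SD 4/8/16 within three
SD-of-sample-SD units; 10,000-replicate null calibration of Welch and
Friedman; exhaustive Fisher enumeration for small tables plus sampled
tables to total 40; and 500 replicate cohorts (n = 52) for the MPI-MAP
correlation, generated without image rasterization — segment-level
measurement noise (~0.03 intensity units at ~5000 px per segment) is two
orders of magnitude below the between-patient SD, so rendering cannot
move the recovered correlation at the tested tolerance.

## Known limitations

* The liver reference is a single maximum: a bright artifact inside the
  liver polygon (e.g. a catheter tip) would corrupt the normalization of
  that image. Real deployments should QC the annotation; the phantom has
  no such artifacts.
* MPI/FHPI are resolution- and smoothing-sensitive at the margins;
  comparisons are only meaningful within a consistently processed stack
  (same target level, same interpolation, same px/mm), which the pipeline
  enforces and records.
* Larger basal ROIs mechanically contain more pixels; FHPI is a per-pixel
  SD and therefore not biased by ROI size, but its sampling error shrinks
  with ROI area, so per-segment FHPI precision varies.
* The cohort generator couples MAP to MPI linearly with Gaussian
  residuals; it cannot emulate nonlinear ventilation-aeration
  relationships.
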