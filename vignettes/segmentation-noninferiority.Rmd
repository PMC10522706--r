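---
title: "Evaluating segmentation agreement with non-inferiority margins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating segmentation agreement with non-inferiority margins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question this package answers

When an automatic model segments a structure whose boundaries experts
themselves disagree about — the ischemic core on non-contrast head CT is the
motivating example — comparing the model to a single "ground truth" rater
answers the wrong question. A Dice of 0.5 against one expert is uninformative
if two experts also agree at Dice 0.5. The meaningful claim is *non-inferiority*:
the agreement between the model and an expert is no worse, up to a margin
representing normal inter-expert variability, than the agreement between two
experts.

`segnoninfer` implements the three parts needed to make that claim
reproducible:

1. a battery of seven agreement metrics for co-registered 3D binary masks on
   anisotropic voxel grids;
2. a paired, margin-based, one-sided testing framework with multiplicity
   control and bootstrap confidence intervals;
3. a synthetic multi-rater lesion cohort generator so the whole pipeline can
   be exercised and calibrated without clinical data.

## Masks and geometry

A mask is a 3D array of 0/1 flags plus the physical voxel spacing in mm
(`seg_mask()`). Volumes are voxel counts times the voxel volume (reported in
ml); distances are Euclidean distances between voxel *centres* with the
spacing applied per axis. Masks are required to live on the same grid —
shapes must match exactly, spacing to a relative tolerance of 1e-4 — and the
package deliberately performs no resampling or registration: resampling a
mask silently changes every metric, so co-registration is an explicit
upstream responsibility. NIfTI input is binarised at 0.5; only spacing is
taken from the header.

## The metric battery

For an ordered (prediction, reference) pair:

* **VS** (volumetric similarity): `1 − |Vp − Vr| / (Vp + Vr)`.
* **AVD**: `|Vp − Vr|` in ml.
* **Dice**, **precision**, **recall** from voxelwise counts.
* **HD95**: the 95th-percentile Hausdorff distance in mm. Each directed
  percentile is computed over the distances from one mask's surface voxels to
  the nearest surface voxel of the other, with linear interpolation between
  order statistics; the symmetric value is the maximum of the two directed
  percentiles. A pooled-percentile variant is available
  (`hd95(..., method = "pooled")`) but the max-of-directed form is the
  default, pinned by brute-force oracle tests.
* **SDT** (surface Dice at tolerance, also called normalised surface Dice):
  the fraction of surface voxels of either mask lying within a tolerance τ
  of the other mask's surface. The default τ = 5 mm reflects that, for
  lesions like the ischemic core, inter-rater variability concentrates on
  the outer boundary.

Surface voxels are foreground voxels with a face-adjacent (6-connected)
background neighbour, with the grid edge counting as background. Distances
use an exact anisotropic separable Euclidean distance transform (compiled
code), which agrees with the all-pairs definition to floating-point
precision; the test suite verifies this on random grids against a literal
all-pairs implementation.

**Empty masks.** Raters may legitimately segment nothing. The conventions
are explicit rather than silent: both masks empty means perfect agreement
(overlap/volume metrics 1, distances 0); exactly one empty means worst
overlap (Dice, VS, SDT = 0), AVD equal to the non-empty volume, undefined
HD95, and undefined precision (empty prediction) or recall (empty
reference). Undefined values carry `defined = FALSE` and are removed
pairwise-complete downstream: a case is dropped for one metric's test only
if either of its two compared values is undefined, and the number used is
reported.

## The non-inferiority framework

Let `a_i` be the inter-expert agreement on case i (test expert vs reference
expert) and `b_i` the model-expert agreement (same test expert vs model) for
one metric. With margin δ the oriented difference is

* higher-is-better metrics: `d_i = b_i − a_i + δ`,
* lower-is-better metrics (AVD, HD95): `d_i = a_i − b_i + δ`,

so that positive values always support non-inferiority; the orientation is
taken from the battery specification, not from the caller. The hypothesis
H1: median(d) > 0 is tested one-sided at α = 0.05. When the Shapiro–Wilk
test does not reject normality of the `d_i` (p ≥ 0.05), a paired t-test is
used; otherwise the one-sided Wilcoxon signed-rank test. The test actually
used is recorded in the result. Applying the margin by shifting the
differences is equivalent, under the paired-shift model, to shifting one
series before ranking; it is stated here because signed-rank tests are not
shift-invariant in general.

The default margins are 20% of the metric range for unit-interval metrics,
3 ml for AVD, and 3 mm for HD95 — rounded bounds of the normal variation of
agreement among experienced raters. `derive_margins()` re-derives such
bounds from data as the mean (over the metrics of each family) of the mean
absolute per-case difference between two inter-expert agreement series.
The averaging scheme is one defensible reading of "average difference in
inter-expert agreement" and is flagged as an interpretation; the rounded
defaults remain operative unless the derived values are passed explicitly.

**Signed-rank details.** Zeros are discarded by default (Wilcoxon's
convention; Pratt's method is available). With ≤ 20 non-zero differences
and no tied magnitudes the p-value is exact (the full null distribution of
the positive-rank sum, verified in tests against 2^n sign enumeration);
otherwise a normal approximation with continuity correction and tie/zero
variance corrections is used. Differences within 1e-10·δ of zero are
snapped to zero, so a model sitting exactly on the margin boundary is
recognised as the degenerate case (p = 1) instead of being decided by
floating-point residue.

**Multiplicity.** All p-values of one battery run are Holm–Bonferroni
adjusted. A library cannot know about tests performed outside it, so the
family defaults to the run; `holm_family_size` lets the analyst declare a
larger family.

**Summaries.** Each series is summarised by its median with a percentile
bootstrap confidence interval (default 10,000 resamples at 95%, seeded and
deterministic; reports always show explicit lower/upper bounds rather than
a ± half-width). Spearman's rank correlation of per-case volumes
(`spearman_rho()`, `plot_volume_agreement()`) complements the overlap
metrics with a volume-agreement view.

## The synthetic cohort generator

`generate_truth()` builds each case as the union of irregular ellipsoids:
per-axis radii set the shape, a target volume drawn from 5–30 ml (the
interquartile range typical of expert-annotated ischemic-core volumes) sets
the scale, and a smooth random field perturbs the level set so boundaries
are not analytic surfaces. The default grid is 64 × 64 × 32 voxels at
(3.6, 3.6, 3.0) mm — a coarsened head-CT geometry with thick slices, chosen
so a full 32-case, four-annotator cohort generates and evaluates in a few
seconds while remaining genuinely anisotropic.

`apply_rater()` simulates an annotator per connected component:

* the component is skipped with probability 1 − `sensitivity`;
* the signed Euclidean distance field of the component is perturbed by a
  smooth random displacement field of scale `boundary_jitter_mm`
  (correlation length ~12 mm). Perturbing the distance field, rather than
  flipping voxels, keeps annotations compact and surface-like — voxel noise
  would create surface debris that degenerates the distance metrics;
* the threshold on the perturbed field is chosen by rank so the annotated
  volume equals `volume_bias` times the true component volume, multiplied
  by symmetric log-normal noise whose coefficient of variation grows with
  the jitter relative to the component's radius. This gives exact control
  of the systematic bias (the median volume ratio recovers `volume_bias`,
  verified to within 10% in tests) while keeping per-case volumes random.

The default panel emulates a three-expert study: a reference rater A
(jitter 3 mm, unbiased), a test rater B (jitter 6 mm, 15% over-segmenter),
a test rater C that under-segments severely (bias 0.35, sensitivity 0.55 —
its median annotated volume sits far below the reference, as a conservative
human rater's can), and a "model" with rater A's parameters but independent
randomness. With this panel the inter-expert Dice medians land near 0.6 and
SDT near 0.75 on the default grid.

What the generator does *not* emulate: CT intensities and their windowing,
anatomical priors (lesions are blobs, not vascular territories),
inter-rater correlation of errors (raters err independently given the
truth), and multi-focal scattered infarcts beyond simple unions. Passing
tests on synthetic cohorts therefore validates the *evaluation machinery* —
metric correctness, calibration, power, reproducibility — not any claim
about real clinical images.

## Numerical and design choices

* Percentiles (HD95, bootstrap CIs) use linear interpolation between order
  statistics (R's default type 7).
* The distance transform is exact (Felzenszwalb–Huttenlocher lower
  envelope per axis with squared spacing weights), not an approximation.
* All randomness is reproducible: every generator call derives per-case,
  per-rater seeds from one master seed, and the bootstrap restores the
  caller's RNG state.
* Minimum usable pairs per test: 5 (below that the exact signed-rank
  distribution cannot reach p < 0.05 one-sided).
* Metrics with fewer than 5 usable pairs are reported with their case
  count and no p-value rather than being dropped from the report.

## Problem sizes used in validation

The test suite validates the surface metrics against a literal all-pairs
brute force on ~200 random grids up to 12³ voxels with mixed isotropic and
anisotropic spacing; the signed-rank test against full 2^n enumeration for
n ≤ 12; type-I error of the non-inferiority test at the margin boundary
over 2000 simulated 32-case cohorts (rejection ≤ 0.065 at α = 0.05);
bootstrap coverage over 1000 replications; and the end-to-end pipeline over
100 simulated 32-case cohorts, in which a reference-like model must be
declared non-inferior on all unit-interval metrics in at least 95% of
replicates and a model degraded by three times each margin in none.

## Worked example

```{r, eval = FALSE}
library(segnoninfer)

cases <- generate_cohort(32, seed = 1)
agreement <- evaluate_cohort(cases)   # B vs A and B vs model, 7 metrics
battery <- run_noninferiority_battery(agreement)
tidy(battery)
glance(battery)
autoplot(battery)

vols <- cohort_volumes(cases)
plot_volume_agreement(vols, "A", "model")
```

## Limitations

* Binary masks only; multi-class or probabilistic segmentations must be
  thresholded upstream.
* No registration or resampling; grids must match.
* The Holm family is the run unless declared otherwise; cross-study
  multiplicity is the analyst's responsibility.
* Non-inferiority margins are scientific choices, not statistical ones;
  the defaults encode one study design and `derive_margins()` is an
  interpretation of margin derivation from variability, not a canonical
  estimator.
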