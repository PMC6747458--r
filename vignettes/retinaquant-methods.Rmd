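---
title: "Quantifying retinal microglia and ganglion cells on synthetic whole mounts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal microglia and ganglion cells on synthetic whole mounts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinaquant)
```

## The problem

Retinal whole mounts immunostained for Iba-1 (microglia) or Brn3a
(retinal ganglion cell nuclei) are the standard read-out for
neuroinflammation and ganglion-cell loss in rodent ocular-hypertension
(OHT) models of glaucoma. The quantities of interest are per-field cell
counts in the strata where microglia tile the tissue (outer and inner
plexiform layers), the percent of retinal area covered by
marker-positive signal where they do not (the nerve fibre/ganglion cell
layer), per-cell morphometry (soma area, arbor area — both change with
microglial activation), counts of the bright puncta formed where
processes cross between the OPL and the photoreceptor outer segments,
and RGC counts. Group comparisons are nonparametric: rank-sum tests
between groups, signed-rank tests between the two eyes of unilaterally
lasered animals, and zone-wise ANOVA with Bonferroni correction.

No image data from such studies is publicly deposited, so this package
pairs the measurement pipeline with a synthetic-field generator that
plants cells with known ground truth. Everything the detector and the
statistics report can therefore be validated against what was planted.

## The counting algorithm

The automatic counter is a segmentation/distance-control chain operating
on a single grayscale field (z-stacks at 2 µm section spacing are first
reduced by a mean projection):

1. **Peak normalization.** The image is divided by its brightest pixel
   so values span [0, 1]. A blank-field guard precedes this step: if the
   raw peak is below an absolute floor (`noise_floor`, default 0.1 in
   relative intensity units), the field is reported as containing zero
   cells. Without the guard, peak normalization of a pure-noise image
   rescales noise to full range and the threshold below becomes
   meaningless.
2. **Threshold with retention.** Values below `low_threshold` (default
   0.2) are set to zero; the remaining values are retained verbatim, not
   binarized. This preserves the most intense structures — normally the
   cell bodies — and keeps intensity information for the next step.
3. **Segmentation.** Connected components of the surviving support,
   8-neighbour connectivity by default so that thin diagonal structures
   do not split a cell.
4. **Centres of mass.** One intensity-weighted centre of mass per
   segment. The weighting is a deliberate choice: on a retained-intensity
   (not binary) image, "centre of mass" naturally means weighting by
   intensity.
5. **Distance control.** Centres closer to each other than
   `min_distance` are merged by the transitive closure of the strict
   "distance < `min_distance`" relation, one representative (the
   centroid of the cluster's members) per cluster, so a cell split over
   adjacent segments is counted once. The output order is deterministic
   (largest member segment first, then (y, x)).

`min_distance` is a free parameter of the method; the defaults are 12 µm
for microglia (about one soma diameter), 8 µm for RGC nuclei and 4 µm
for vertical-process spots. The same chain counts all three cell
classes; only the parameters change.

The percent-area measure (`area_fraction()`) thresholds the normalized
image and reports `100 * n_above / n_total`. The original protocol
adjusted this threshold manually; here the default is Otsu's method with
a numeric override, and the threshold actually used is always part of
the result.

## Morphometry

The study this package emulates measured soma and arbor area by hand.
The automated proxies are:

- **Soma area**: the connected region around the detected centroid above
  half of the cell's own peak (the full-width-at-half-maximum
  convention), after subtracting the local background (median of the
  isolation crop). The half-max convention makes the measure invariant
  to global intensity scale, and the synthetic soma profile is built so
  its half-max contour sits exactly at the planted radius.
- **Arbor area**: the cell's support above a low fraction (default 0.08)
  of its peak is skeletonized (Zhang–Suen thinning); skeleton endpoints
  are taken as process tips and the convex hull of tips plus soma
  boundary is returned. Two discretization corrections are applied:
  endpoints are snapped outward (≤ 3.5 µm) to the distal-most support
  pixel of their arm, because thinning retracts blunt line ends by a few
  pixels; and endpoints adjacent to signal removed by the isolation mask
  are discarded, because they mark where a neighbouring cell's structure
  was cut off, not a process tip. The convex hull is an upper envelope
  of the hand-drawn simple polygon it replaces, and a process-free cell
  degrades to the hull of its soma (so arbor ≥ soma always).

Cells are measured in isolation: a crop (default 70 µm) around the
centroid in which pixels nearer to a competing centroid are masked out
(nearest-centroid assignment), mirroring the fact that the manual
protocol measures cells individually.

The original study measured these quantities in four
eccentricity-defined areas per retina; the exact eccentricity geometry
is not reconstructible, so the pipeline samples a configurable number of
fields per retinal zone instead — a documented deviation.

## The synthetic generator

The generator is first-class, tested code, not a fixture. It emulates:

- **Field geometry.** Square fields of 0.1502 mm², the area of one 20×
  photomicrograph in the emulated protocol, at 1024 × 1024 px by default
  (≈ 0.3786 µm/px; the protocol states the field area but not the pixel
  size).
- **Ramified microglia** as a smooth soma disc (supergaussian profile,
  half-max exactly at the soma radius) plus 4–6 tapering process ridges.
  Process intensity is 0.42 of the cell peak at the base, decaying
  rapidly to a distal plateau of 0.12: the proximal stub survives the
  global 20 % threshold (so each cell yields one compact segment) while
  the distal arbor remains measurable per cell above background. Ridge
  width is floored at the pixel pitch so processes do not alias apart at
  coarse samplings.
- **Mosaic placement.** Rejection sampling with pairwise centre
  distances ≥ 2 × the profile-scaled mean arbor radius; an infeasible
  packing raises an error rather than silently dropping cells.
- **Activation** as multiplicative factors on density, soma radius,
  arbor radius and vertical-spot count. The preset magnitudes (OHT:
  density 1.3, soma 1.5, arbor 0.7, spots 1.4; saffron-treated OHT
  attenuated to 1.1/1.15/0.9/1.3; RGC survival 0.75 under OHT, 0.95 with
  treatment, with an extra 0.85 superior-zone factor under OHT) are
  **illustrative configuration**: the emulated study reports its effect
  sizes only as figure histograms, so no numeric magnitude here is a
  literature value. They were chosen once, before any validation runs,
  to be large unambiguous effects with the reported directions.
- **RGC nuclei** as dense, round, process-free blobs (radius ≈ 3.2 µm,
  ≥ 9 µm spacing, 120 per field at baseline — a deliberately desk-scale
  density), and **vertical-process spots** as small puncta (radius
  1.5 µm, below the microglial soma diameter by construction).
- **Noise**: a low uniform background (0.05) plus additive Gaussian
  noise (SD 0.01), clipped at zero — the simplest model that exercises
  the normalize-then-threshold chain.
- **Z-stacks**: 5 sections at 2 µm spacing sharing the in-plane pattern
  with a triangular intensity profile and independent per-section noise,
  which is what makes the mean projection meaningful.
- **Study structure**: the full design (`paper_design()`) has a naive
  control (n = 6), a saffron control (n = 8), lasered and
  saffron + lasered cohorts with paired OHT/contralateral eyes (n = 8 at
  day 3 for the microglia arm, n = 6 at day 7 for the RGC arm). Animal
  identity is a shared log-normal density multiplier (SD 0.06) across
  both eyes, which is what gives the signed-rank pairing its
  correlation. Per-field planted counts add ± 8 % uniform jitter.

What the generator does **not** emulate: optics (no PSF beyond the
profile smoothness), multi-channel labelling, vasculature or non-mosaic
cell arrangements, intensity inhomogeneity across the field, and the
contiguous meridian-scanning field layout of the real protocol (retina
dimensions are not reconstructible; the zone × field grid is the
documented approximation). Passing tests therefore demonstrate that the
measurement chain is correct under the stated image model, not that it
is robust to every artifact of real micrographs.

## Statistics

`mann_whitney_u()` and `wilcoxon_signed_rank()` are two-sided
throughout (the emulated comparisons are symmetric "vs." contrasts).
The exact path is used up to 12 observations (pooled for the rank-sum
test, nonzero pairs for the signed-rank test): tie-free cases use the
closed-form null distributions (`pwilcox`, `psignrank`); tied absolute
differences in the signed-rank test fall back to full enumeration of the
2^m sign patterns on mid-ranks. Larger samples use the tie-corrected
normal approximation, and the method used is always recorded in the
result. Zero differences are dropped (the test's original convention)
and counted in the output. `anova_bonferroni()` is the standard one-way
F test plus pooled-SD pairwise t tests with Bonferroni adjustment.

Two statistical properties deserve explicit mention:

- **Discreteness of exact tests.** At n = 6 or 8 pairs the exact
  signed-rank test cannot reject at exactly 5 %: its attained sizes are
  0.031 and 0.039. The null-calibration checks in the test suite
  therefore use n = 7 pairs (attained size 0.047) for the signed-rank
  test, 6 vs 8 for the rank-sum test (attained size 0.043 on its normal
  path) and 4 × 6 for the ANOVA — all within the emulated study's group
  sizes. This is a property of exact small-sample tests, not of this
  implementation.
- **No correction across metrics.** Bonferroni correction is applied
  only within the zone-wise ANOVAs, mirroring the emulated analysis;
  the many layer × metric comparisons in the grid are uncorrected. This
  is a faithful reproduction and a known limitation.

The default unit of analysis is the per-animal (per-eye) mean over
fields; `aggregate_fields()` also exposes field-level passthrough, since
the emulated analysis does not state its unit explicitly.

## Problem sizes and numerical choices

Study-scale runs in this package default to reduced sizes chosen to keep
a full run interactive: 256 px fields (same 0.1502 mm² physical area;
calibrated measures are resolution-equivariant), 8 fields per retina
against the ~550 of the full protocol, and 4 morphometry cells per
field. `pattern_design()` is smaller still (5 single-eye groups, n = 4,
4 fields, OPL + NFL-GCL only) and exists for repeated end-to-end
direction checks; the full paired design remains `paper_design()`, and
full scale is reachable through the design arguments. The direction
checks codify "treated ≈ naive" for RGC counts as recovery — the treated
group above the untreated OHT group and deviating from naive by less
than the OHT deficit.

Numerical conventions: physical coordinates are pixel centres
(`(index - 0.5) × pixel_size`, x along columns); ties in de-duplication
are broken by largest segment then (y, x) order so output is
deterministic; the merge relation is strictly "closer than"
`min_distance`, so centres at exactly the minimum distance remain
distinct; all randomness flows through explicit seeds (the generators
save and restore the caller's RNG state); 16-bit TIFF output records its
intensity scale in a JSON sidecar so physical intensities round-trip.

## Known limitations

- Soma areas are inflated by roughly 20–30 % where bright process bases
  join the soma; the half-max region leaks a short distance along each
  stub. Ratios between conditions, which is what the study design
  compares, are essentially unaffected (factor recovery is within a few
  percent), but absolute soma areas should not be read as exact disc
  areas.
- Arbor measurement degrades below ~1.5 µm/px: thin distal processes
  alias and hulls shrink. The hull-containment guarantee is validated at
  the native ≈ 0.4 µm/px sampling.
- In dense activated fields, arbors of neighbouring cells genuinely
  touch; the isolation mask then truncates both, and arbor areas carry a
  small downward bias there.
- The 3-D structure of the tissue is reduced to 2-D fields per layer;
  no volumetric segmentation is attempted.
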