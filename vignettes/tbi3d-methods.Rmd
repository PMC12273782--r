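---
title: "Layer-by-layer 3D quantification of TBI pathology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layer-by-layer 3D quantification of TBI pathology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbi3d)
```

## The problem

A controlled cortical impact (CCI) produces a cavity of lost tissue in one
hemisphere of the mouse brain, and a halo of secondary pathology — vessel
loss, blood-brain-barrier leakage (dextran extravasation), and hypoxia —
that decays with distance from the lesion. Whole-brain light-sheet imaging
of cleared tissue yields multi-channel 3D volumes in which these effects can
be quantified without sectioning artifacts. Because injured brains deform
unpredictably, atlas registration is unreliable; `tbi3d` instead measures
everything *relative to the lesion itself*: it segments the cavity, derives
conformal depth layers (shells at fixed distance intervals from the lesion
boundary), and reports each pathology metric per layer, normalized by that
layer's tissue volume. All reporting is in mm and mm^3; internal distances
are in micrometers.

## Pipeline stages and their models

### Tissue and lesion geometry

1. **Tissue segmentation.** The dextran channel carries tissue
   autofluorescence, so thresholding it (fixed value or Otsu's
   between-class-variance criterion for `"auto"`) separates tissue from
   camera background; the largest connected component is kept.
2. **Surface solidification.** Morphological closing with a ball of
   physical radius (default 300 um) followed by hole filling bridges the
   cavity mouth and produces a solid brain envelope. The mask is padded by
   the ball radius before closing so dilation is never clipped at the array
   border; with that padding, closing is exactly idempotent on convex
   rasters. The closing radius must exceed the half-width of the cavity
   mouth to bridge it; 300 um comfortably covers a 1-mm-class impact
   cavity at the lesion-analysis resolution.
3. **Midsagittal plane.** The center of mass of the solid mask along the
   left-right axis defines the fractional plane position.
4. **Mirror-subtraction lesion mask.** The tissue mask is reflected across
   the plane, rigidly aligned to the original by the integer translation
   maximizing overlap (FFT cross-correlation, search radius 10 voxels), and
   the lesion is mirrored-contralateral-tissue AND NOT ipsilateral-tissue,
   restricted to the ipsilateral half. The subtraction must run against the
   *tissue* map, not the solidified envelope — the envelope has the cavity
   filled by construction, so subtracting against it can never reveal
   missing tissue — and the mirrored tissue itself bounds the lesion
   region, so no envelope restriction is needed (clipping to the rolling-
   ball hull would shave the cavity's mouth dome). Components
   below 1e-3 mm^3 are dropped; this size filter and the side restriction
   are automated stand-ins for manual mask refinement and are exposed as
   configuration, not claimed equivalent to a human annotator.
5. **Lesion boundary.** Tissue voxels 6-adjacent to the lesion (or to the
   exterior where the cavity opens to the surface) form the seed surface
   for layering. For sham brains with an empty lesion an optional
   craniotomy-window seed can be supplied.

Registration is translation-only. Near-symmetric brains (and the phantom)
do not require rotation, and a deterministic translation search keeps the
lesion mask reproducible; the search radius is configuration.

### Conformal depth layers

Layer `k` is the set of tissue voxels (outside the lesion) whose Euclidean
distance from the lesion-plus-boundary seed falls in
`[(k-1) t, k t)` with thickness `t = 100` um by default and 10 layers
(out to 1 mm). Two constructions are provided:

- `"edt"` (default): bin the exact anisotropic Euclidean distance
  transform at multiples of `t`. This is the continuous-distance analogue
  of repeated spherical dilation, works for anisotropic spacing, and costs
  one distance transform regardless of the layer count.
- `"dilation"`: iterate binary dilation with a rasterized sphere of
  `floor(t / spacing)` voxels radius (100 um at 5.37 um spacing = 18
  voxels; a voxel belongs to the sphere when its center lies within the
  radius, ties included) and take successive differences. This is the
  literal reference construction; it requires isotropic spacing.

`layers_equivalence_check()` cross-validates the two (per-layer Jaccard,
>= 0.9 on the test phantoms; the difference is the cumulative overshoot of
iterated discrete dilation). Distance is measured from the solid lesion
together with its boundary, so layer 1 starts at the lesion surface —
matching the "0 to 100 um" reading of the layer intervals. Seeding from
the hollow boundary alone would shift layers by at most one voxel on the
phantoms; the solid seed was chosen and is fixed.

### Vasculature

Vessels are bright tubes in the lectin channel. The multi-scale Frangi
vesselness filter diagonalizes the gamma = 1 scale-normalized Hessian
(second derivatives times sigma^2) per voxel; with eigenvalues ordered
`|l1| <= |l2| <= |l3|` the response is

V = (1 - exp(-R_A^2 / 2 alpha^2)) * exp(-R_B^2 / 2 beta^2) * (1 - exp(-S^2 / 2 c^2))

where `R_A = |l2|/|l3|` separates lines from plates, `R_B = |l1|/sqrt(|l2 l3|)`
suppresses blobs, and the structureness `S = sqrt(l1^2+l2^2+l3^2)` gates
noise, wherever `l2, l3 < 0` (bright tubes), zero elsewhere; the response is
maximized over scales. Defaults follow the filter's source conventions:
`alpha = beta = 0.5`, `c` data-adaptive at half the maximum Hessian norm
per scale, scales 3/6/12/24 um spanning capillaries to penetrating
vessels. The source workflow does not state its threshold or scales, so
all of these are configuration, and every test states its own values.

The thresholded vesselness mask is thinned to a one-voxel centerline by
sequential (26, 6) simple-point deletion in six directional subiterations,
preserving curve endpoints. The skeleton graph connects 26-adjacent
centerline voxels; per-node radius is the Euclidean distance transform of
the vessel mask at the node; edge length is the physical voxel step. Vessel
volume is the cylinder/frustum sum `pi rbar^2 l` per edge — derived from
the extracted centerline and radius features rather than by counting mask
voxels — with branch-point radii (degree >= 3) replaced by the non-branch
neighbor's radius, because the distance transform overestimates radius at
junctions. Each edge is assigned to the depth layer containing its
midpoint: an unambiguous partition whose error is bounded by one edge
length. Length density is reported in mm of centerline per mm^3 of layer
tissue (the figure-ready normalization; the source reports "per tissue
volume" without printing units, so the unit choice is documented here).

Known discretization behavior, measured on rasterized cylinders: the
centerline retreats about half a radius at open tube ends (identical to
Lee-style thinning in the standard reference implementations), so total
length of a finite tube is underestimated by about `r` while the interior
length is exact; radii below about 3 voxels carry a positive half-voxel
bias that inflates `r^2` by ~20%, so the vessel-analysis resolution should
keep expected radii at or above 3 voxels (the 2x downsampled 2.68-um
channel does this for capillaries). Restriction of vessel analysis to the
perilesional layered region stands in for a cortex mask; no atlas is used.

### Hypoxia and extravasation

Dyes that cannot cross an intact blood-brain barrier accumulate near the
lesion only, so the uninjured hemisphere provides a per-brain background
reference. The threshold is the 99.9th percentile (linear-interpolation
quantile, fixed for reproducibility) of intensities in the *distal half*
of the contralateral tissue — the distal restriction keeps perilesional
signal that spills across the midline out of the reference. Comparison is
strictly greater, so a constant background yields zero signal. Supra-
threshold voxels inside tissue, minus components below 1e-4 mm^3 (a
documented stand-in for the unspecified denoising step of the source
workflow, not a reproduction of it), are summed per layer and divided by
layer tissue volume. Thresholds are always per-brain; a threshold computed
on one brain is never applied to another.

### Group statistics and qPCR

Per metric and per layer, with one value per animal: 1.5 x IQR outlier
removal (type-7 quartiles, closed fences, lists shorter than 4 pass
through), one-way ANOVA, and Fisher's LSD post hoc pairwise comparisons
(pooled within-group variance, no multiplicity adjustment — LSD is
unadjusted by definition), at significance 0.05. Layers are analyzed
separately, never pooled, matching the per-layer box-plot design.
qPCR fold changes use per-animal `dCt = Ct_target - Ct_reference`
(GAPDH-style housekeeping reference), group-mean
`ddCt = mean dCt(treated) - mean dCt(control)`, fold change `2^-ddCt`, and
an unpaired two-tailed pooled-variance t test on the per-animal dCt values.
Whether the point estimate should instead average per-animal `2^-ddCt`
values is not determined by the source description; the group-mean form is
implemented and the per-animal dCt vectors are returned so the alternative
can be computed.

## The synthetic phantom

`phantom_spec()` / `rasterize_phantom()` generate the ground-truthed inputs
every stage is tested against: a bilaterally symmetric ellipsoidal brain
with uniform autofluorescence, a recursive bifurcating vessel tree (straight
branches, radius decaying by 0.75 per bifurcation, deflection 20-60 degrees,
termination at 1.5 voxels radius or at the tissue surface), an ellipsoidal
cavity opening to the dorsal surface strictly inside one hemisphere,
perilesional signal decaying as `exp(-d / 150 um)` from the cavity surface
(zeroed contralaterally beyond three decay lengths), and i.i.d. Gaussian
noise. The exponential falloff is a modeling choice — the source reports
signal "predominantly near the injury site" without a spatial model — and
its decay length is configurable so tests can place known signal volumes in
known layers. Geometry and noise take separate seeds so cohorts can share
anatomy while varying noise; every output is bit-reproducible given the
seeds.

Ground truth is computed independently of the measurement path: cavity
volume by refined (half-voxel) rasterization of the two ellipsoids; vessel
length/volume analytically from the segment list, binned by segment-midpoint
distance to the lesion surface (point-to-ellipsoid distance via the Lagrange
parameter root); supra-background signal volume from the deterministic
signal field at the `z = 3.0902` Gaussian false-positive point.

What the phantom does *not* emulate: curved vessels, capillary anastomoses
(the truth tree is acyclic), the point-spread function and shadowing of
light-sheet optics, spatially varying autofluorescence, and anatomically
realistic brain geometry. Passing tests therefore demonstrate that the
algorithms recover known geometry and intensity structure under noise, not
that biological effect sizes from real brains are reproduced.

Default phantom study conditions (used by the test suite and the acceptance
script, chosen once at desk scale): brains of semi-axes 250-360 um at 12 um
isotropic spacing (roughly 60^3 voxels), 3 vessel trees of root radius
30 um, a 130-150 um semi-axis cavity, signal decay length 100-150 um,
autofluorescence 100, signal peak 300, vessel intensity 400, noise sd
15-20. The layering cross-validation runs on a ~128^3 grid at 5 um. Cohort
calibration uses 20 repetitions of 3-brain groups. These sizes keep the
full suite within minutes on one CPU while leaving every structure
(vessel radii, layer thickness, cavity mouth) several voxels wide.

## Numerical choices

- Index order is `(z, y, x)` with R's 1-based indices; physical coordinate
  `= (index - 1) * spacing + origin`. The left-right axis defaults to axis
  3 and the ipsilateral side to the high-index half.
- Downsampling is block-mean (not striding or max): it preserves the
  intensity normalization the thresholds rely on; trailing partial blocks
  average over the voxels present so border tissue is not discarded.
- The distance transform is the exact anisotropic squared-distance
  algorithm (lower envelope of parabolas per axis), so dilation/erosion by
  a physical-radius ball are tie-inclusive thresholds of it.
- Sphere rasterization includes voxels whose center lies within the
  radius, ties included.
- Hole filling classifies background 6-components not touching the array
  border as holes.
- Degenerate inputs: empty vessel masks yield empty graphs (not errors);
  layers with signal or vessels but zero tissue volume report `NA` with a
  warning rather than infinity; an all-identical ANOVA errors, while zero
  within-group variance with unequal means reports p = 0 with a warning.
- Everything after the phantom is deterministic: reruns of `run_brain()`
  with the same configuration are byte-identical, and the manifest records
  every parameter plus the package version.

## File formats

Volumes and masks travel as NRRD (raw-encoded, with per-axis spacing and
origin metadata; the package's native format) or multi-page 16-bit TIFF
stacks (no spacing metadata; callers supply it). Metric tables are CSV with
a header row; reports and manifests are JSON. The package consumes single-
resolution fused volumes; multi-resolution pyramids and tile stitching are
upstream concerns and out of scope.

## Known limitations

- Mirror registration is translation-only; strongly rotated or asymmetric
  brains would need a rigid registration the pipeline does not provide.
- The lesion boundary for sham animals (near-zero lesions) is exposed as a
  craniotomy-window seed option; the source procedure for shams is not
  recoverable from its description.
- Skeleton length at open tube ends retreats by about half a radius; tube
  networks with many free ends are correspondingly underestimated.
- Vessel radii below ~3 voxels are biased high by the distance transform;
  choose the analysis resolution accordingly.
- The component-size denoising stand-ins are documented approximations of
  unspecified steps in the source workflow.
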