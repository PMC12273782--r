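# tbi3d — layer-by-layer 3D quantification of traumatic brain injury pathology

Controlled cortical impact (CCI) leaves a cavity of lost tissue in one
hemisphere of the mouse brain and a halo of secondary damage — vessel loss,
blood–brain-barrier leakage, hypoxia — that fades with distance from the
lesion. Whole-brain light-sheet volumes of cleared tissue capture all of it,
but injured brains deform too unpredictably for atlas registration. `tbi3d`
quantifies pathology **relative to the lesion itself**:

1. **Lesion segmentation** — threshold the autofluorescence channel,
   solidify the brain surface (ball closing + hole fill), split hemispheres
   at the center-of-mass midsagittal plane, and subtract the mirrored
   uninjured hemisphere from the injured one. Lesion volume is the summed
   voxel volume in mm³.
2. **Conformal depth layers** — disjoint 100-µm shells at increasing
   Euclidean distance from the lesion boundary (exact distance-transform
   binning, with the iterated 18-voxel spherical-dilation construction kept
   as a cross-check).
3. **Vasculature** — multi-scale Frangi vesselness
   `V = (1−e^{−R_A²/2α²})·e^{−R_B²/2β²}·(1−e^{−S²/2c²})` on the Hessian
   eigenvalues (|λ₁|≤|λ₂|≤|λ₃|, λ₂,λ₃<0 for bright tubes), topological
   thinning to centerlines, radii from the Euclidean distance transform,
   per-layer length density (mm/mm³) and volume fraction (mm³/mm³).
4. **Hypoxia & extravasation** — per-brain thresholds at the 99.9th
   percentile of the uninjured contralateral hemisphere; supra-threshold
   volume per layer, normalized by layer tissue volume.
5. **Group statistics** — 1.5×IQR outlier removal, one-way ANOVA with
   Fisher's LSD post hoc per metric per layer, and 2^−ΔΔCt qPCR fold
   changes with unpaired two-tailed t tests.

A ground-truthed synthetic brain phantom (symmetric tissue ellipsoid,
branched bright-tube vessel tree, surface-opening cavity, exponentially
decaying perilesional signal, Gaussian noise) makes every stage testable
without animal data.

## Worked example

```r
library(tbi3d)

spec <- phantom_spec(
  brain_semi_axes = c(300, 330, 360), spacing = 12, n_trees = 3,
  root_radius = 30, branching_depth = 3, branch_length_um = 200,
  min_radius = 14, lesion_center = c(-240, 0, 170),
  lesion_semi_axes = c(150, 140, 130), signal_decay_length = 100,
  noise_sd = 15, seed = 42)
ph <- rasterize_phantom(spec)
ph$truth$lesion_volume_mm3
#> [1] 0.006242616

tissue <- segment_tissue(ph$extravasation, "auto")
solid  <- solidify_surface(tissue, 250)
plane  <- find_midsagittal(solid, lr_axis = 3)
lesion <- mirror_subtract_lesion(solid, plane, ipsilateral_side = 1,
                                 tissue = tissue)
mask_volume_mm3(lesion)
#> [1] 0.006225984

boundary <- lesion_boundary(lesion, solid)
layers   <- build_layers(boundary, tissue, lesion, layer_spec(100, 4))
layers
#> <depth_layer_set> 4 layers of 100 um (edt method)
#>   [   0,  100) um: 0.0214 mm3 tissue
#>   [ 100,  200) um: 0.0348 mm3 tissue
#>   [ 200,  300) um: 0.0419 mm3 tissue
#>   [ 300,  400) um: 0.0343 mm3 tissue

vness <- frangi_vesselness(ph$vessel, vesselness_params(scales_um = c(12, 24)))
skel  <- skeletonize_vessels(segment_vessels(vness, threshold = 0.2))
skel
#> <skeleton_graph> 217 nodes, 243 edges, total length 3.895 mm
vessel_metrics_per_layer(skel, layers)[, c(1, 2, 6, 7)]
#>   d_min_um d_max_um length_density_mm_per_mm3 volume_fraction
#> 1        0      100                 92.177447     0.049823665
#> 2      100      200                 38.842812     0.025569332
#> 3      200      300                  7.886515     0.009397999
#> 4      300      400                  7.072242     0.008037200

contra <- contralateral_mask(tissue, plane)
thr <- background_threshold(ph$hypoxia, contra, percentile = 99.9)
thr
#> [1] 173.9943
hyp <- segment_signal(ph$hypoxia, thr, tissue)
signal_fraction_per_layer(hyp, layers)[, c("d_min_um", "signal_fraction")]
#>   d_min_um signal_fraction
#> 1        0       0.9964401
#> 2      100       0.2862529
#> 3      200       0.0000000
#> 4      300       0.0000000
```

Reading the output: the recovered lesion volume (0.0062 mm³) matches the
phantom's carved-cavity truth to 0.3%; vessel length density and volume
fraction fall off with depth because the phantom's trees thin toward the
dorsal surface where the lesion sits; the hypoxia threshold lands at the
autofluorescence level (100) plus ≈3.1 noise standard deviations (15), and
the supra-threshold fraction decays from ~1 at the lesion surface to zero
beyond two decay lengths — the programmed exponential falloff.

The same workflow runs from one call per brain (`run_brain()`) or for a
whole cohort with per-layer ANOVA + LSD (`run_cohort()`); a thin CLI over
these functions lives at `inst/scripts/tbi3d.R`
(`tbi3d.R phantom|run|stats --key value ...`). Volumes travel as NRRD or
multi-page TIFF; tables as CSV; reports and manifests as JSON.

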