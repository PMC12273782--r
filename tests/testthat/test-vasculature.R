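frangi_default <- vesselness_params(scales_um = c(4, 8))

test_that("vesselness vanishes on constant fields and rejects tiny grids", {
  g <- voxel_grid(array(50, c(20, 20, 20)), 2)
  v <- frangi_vesselness(g, frangi_default)
  expect_true(all(v$values == 0))
  expect_error(frangi_vesselness(voxel_grid(array(1, c(1, 1, 1)), 1)),
               "Hessian")
})

test_that("vesselness singles out bright tubes and suppresses spheres", {
  d <- c(40, 40, 40)
  idx <- which(array(TRUE, d), arr.ind = TRUE)
  cyl <- array(0, d)
  cyl[idx[(idx[, 2] - 20)^2 + (idx[, 3] - 20)^2 <= 25, , drop = FALSE]] <- 100
  sph <- array(0, d)
  sph[idx[rowSums(sweep(idx, 2, 20)^2) <= 25, , drop = FALSE]] <- 100

  vc <- frangi_vesselness(voxel_grid(cyl, 2), frangi_default)
  vs <- frangi_vesselness(voxel_grid(sph, 2), frangi_default)
  axis_resp <- mean(vc$values[10:30, 20, 20])
  bg_resp <- mean(vc$values[, 5, 5])
  expect_gt(axis_resp, 10 * max(bg_resp, 1e-6))
  # blob suppression: peak at the sphere center below peak on the tube axis
  expect_lt(vs$values[20, 20, 20], max(vc$values[10:30, 20, 20]))

  # contrast monotonicity at fixed c
  p_fixed <- vesselness_params(scales_um = c(4, 8), c = 50)
  v1 <- frangi_vesselness(voxel_grid(cyl, 2), p_fixed)
  v2 <- frangi_vesselness(voxel_grid(2 * cyl, 2), p_fixed)
  expect_true(all(v2$values[20, 20, 20] >= v1$values[20, 20, 20]))
})

test_that("vessel segmentation thresholds and filters components", {
  z <- voxel_grid(array(0, c(10, 10, 10)), 2)
  expect_equal(sum(segment_vessels(z, 0.5, 0)$values), 0)
  expect_error(segment_vessels(z, 1.5), "threshold")
  expect_error(segment_vessels(z, 0), "threshold")

  # a noise-free tube is recovered within 25% of its analytic volume
  tube <- cylinder_mask(40, 4, spacing = 2)
  g <- voxel_grid(tube$values * 100, 2)
  v <- frangi_vesselness(g, frangi_default)
  seg <- segment_vessels(v, 0.2, 0)
  analytic <- pi * (4 * 2)^2 * (40 * 2) * 1e-9
  expect_equal(mask_volume_mm3(seg), analytic, tolerance = 0.25)

  # two components, one below the size filter: exactly one survives
  two <- array(0, c(30, 20, 20))
  two[5:25, 8:12, 8:12] <- 1   # large block
  two[2, 2, 2] <- 1            # single voxel
  vg <- voxel_grid(two * 0.9, 2)
  kept <- segment_vessels(vg, 0.5, min_component_mm3 = 1e-7)
  expect_equal(attr(label_components(kept), "ncomp"), 1L)
})

test_that("a straight tube skeletonizes to a single centered path", {
  r <- 4
  tube <- cylinder_mask(100, r, spacing = 2.68)
  sk <- skeletonize_vessels(tube)
  expect_equal(sum(sk$nodes$degree == 1), 2)      # two endpoints
  expect_equal(sum(sk$nodes$degree >= 3), 0)      # no branches
  # total length: axis length minus cap retreat (~r/2 per end)
  expect_lte(abs(sum(sk$edges$length_um) - 99 * 2.68), 2 * r * 2.68)
  # interior (cap-excluded) length is exact: consecutive unit steps
  lo <- min(sk$nodes$i); hi <- max(sk$nodes$i)
  interior <- sk$nodes$i >= lo + 2 & sk$nodes$i <= hi - 2
  n_int <- sum(interior)
  keep <- which(interior)
  e_int <- sk$edges[sk$edges$from %in% keep & sk$edges$to %in% keep, ]
  expect_equal(sum(e_int$length_um), (n_int - 1) * 2.68, tolerance = 0.02)
  # the centerline sits on the tube axis
  expect_true(all(sk$nodes$j == sk$nodes$j[1]))
  expect_true(all(sk$nodes$k == sk$nodes$k[1]))
  # median radius within 0.5 voxel of truth
  expect_lt(abs(stats::median(sk$nodes$radius_um) / 2.68 - r), 0.5)
})

test_that("skeleton handles isolated voxels and Y junctions", {
  m <- array(FALSE, c(9, 9, 9))
  m[5, 5, 5] <- TRUE
  sk <- skeletonize_vessels(binary_mask(m, 1))
  expect_equal(nrow(sk$nodes), 1L)
  expect_equal(nrow(sk$edges), 0L)
  expect_equal(sk$nodes$degree, 0L)

  expect_equal(nrow(skeletonize_vessels(
    binary_mask(array(FALSE, c(5, 5, 5)), 1))$nodes), 0L)

  # Y: three one-voxel-wide arms meeting at a center voxel
  y <- array(FALSE, c(21, 21, 5))
  y[1:11, 11, 3] <- TRUE              # stem
  for (t in 1:8) {
    y[11 + t, 11 + t, 3] <- TRUE      # upper arm
    y[11 + t, 11 - t, 3] <- TRUE      # lower arm
  }
  sky <- skeletonize_vessels(binary_mask(y, 1))
  expect_equal(sum(sky$nodes$degree >= 3), 1L)
  expect_equal(sum(sky$nodes$degree == 1), 3L)
})

test_that("oblique tubes keep their length and rotations preserve it", {
  r <- 4
  ob <- oblique_cylinder_mask(80, r, spacing = 1)
  sk <- skeletonize_vessels(ob)
  # interior length along the 45-degree axis: compare the end-to-end span of
  # the centerline against the summed edge lengths
  span <- sqrt(sum((as.numeric(sk$nodes[which.max(sk$nodes$i), 1:3]) -
                      as.numeric(sk$nodes[which.min(sk$nodes$i), 1:3]))^2))
  expect_equal(sum(sk$edges$length_um), span, tolerance = 0.02)
  expect_lte(abs(sum(sk$edges$length_um) - 80), 2 * r * sqrt(2))

  # rotation robustness; a long tube keeps end-cap effects below 1%
  tube <- cylinder_mask(250, 3, spacing = 1)
  rot <- binary_mask(aperm(tube$values, c(2, 1, 3)), 1)
  l1 <- skeleton_total_length_mm(skeletonize_vessels(tube))
  l2 <- skeleton_total_length_mm(skeletonize_vessels(rot))
  expect_equal(l1, l2, tolerance = 0.01)
})

test_that("EDT radius at the centerline recovers cylinder radii within half a voxel", {
  for (r in c(2, 4, 6, 8)) {
    tube <- cylinder_mask(60, r, spacing = 1)
    sk <- skeletonize_vessels(tube)
    lo <- min(sk$nodes$i); hi <- max(sk$nodes$i)
    interior <- sk$nodes$i >= lo + 2 & sk$nodes$i <= hi - 2
    expect_lt(abs(stats::median(sk$nodes$radius_um[interior]) - r), 0.5)
  }
})

test_that("per-layer vessel metrics recover an analytic cylinder and conserve totals", {
  tube <- cylinder_mask(50, 4, spacing = 2, pad = 5)
  lay_tissue <- full_mask(dim(tube$values), 2)
  lesion <- empty_mask_like(lay_tissue)
  lesion$values[1, , ] <- TRUE # planar seed face
  layers1 <- build_layers(empty_mask_like(lay_tissue), lay_tissue, lesion,
                          layer_spec(200, 1, "edt"))
  sk <- skeletonize_vessels(tube)
  tab1 <- vessel_metrics_per_layer(sk, layers1)
  L_mm <- skeleton_total_length_mm(sk)
  V_mm3 <- sum(pi * (4 * 2)^2 * sk$edges$length_um) * 1e-9
  Tvol <- layers1$tissue_volumes_mm3[1]
  expect_equal(tab1$length_density_mm_per_mm3[1], L_mm / Tvol,
               tolerance = 0.10)
  expect_equal(tab1$volume_fraction[1], V_mm3 / Tvol, tolerance = 0.10)

  # empty skeleton: all metrics zero
  empty_sk <- skeletonize_vessels(empty_mask_like(lay_tissue))
  tab0 <- vessel_metrics_per_layer(empty_sk, layers1)
  expect_true(all(tab0$length_mm == 0 & tab0$volume_mm3 == 0))

  # partition conservation across many covering layers
  layers_many <- build_layers(empty_mask_like(lay_tissue), lay_tissue,
                              lesion, layer_spec(20, 10, "edt"))
  tab <- vessel_metrics_per_layer(sk, layers_many)
  expect_equal(sum(tab$length_density_mm_per_mm3 * tab$tissue_volume_mm3),
               skeleton_total_length_mm(sk), tolerance = 1e-6)
  expect_equal(sum(tab$volume_mm3),
               sum(pi * tbi3d:::edge_radii(sk)^2 * sk$edges$length_um) * 1e-9,
               tolerance = 1e-9)
})

test_that("a layer with vessels but no tissue reports a missing value", {
  tube <- cylinder_mask(18, 3, spacing = 2, pad = 6)
  tissue <- full_mask(dim(tube$values), 2)
  lesion <- empty_mask_like(tissue)
  lesion$values[1, , ] <- TRUE
  layers <- build_layers(empty_mask_like(tissue), tissue, lesion,
                         layer_spec(20, 3, "edt"))
  layers$tissue_volumes_mm3[2] <- 0 # simulate an empty shell
  sk <- skeletonize_vessels(tube)
  expect_warning(tab <- vessel_metrics_per_layer(sk, layers), "zero tissue")
  expect_true(is.na(tab$length_density_mm_per_mm3[2]))
})
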