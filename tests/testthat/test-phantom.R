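test_that("vessel tree generation is deterministic and collinear when unbranched", {
  spec <- small_phantom_spec()
  s1 <- generate_vessel_tree(spec)
  s2 <- generate_vessel_tree(spec)
  expect_identical(s1, s2)

  # a different seed moves the tree
  s3 <- generate_vessel_tree(spec, seed = 99L)
  expect_false(isTRUE(all.equal(s1, s3)))

  # branching_depth 0, one tree: exactly segments_per_branch collinear
  # segments with total length branch_length_um
  spec0 <- phantom_spec(brain_semi_axes = c(2000, 2000, 2000), spacing = 12,
                        branching_depth = 0L, n_trees = 1L,
                        segments_per_branch = 5L, branch_length_um = 300,
                        lesion_center = NULL, seed = 3L)
  segs <- generate_vessel_tree(spec0)
  expect_equal(nrow(segs), 5L)
  lens <- sqrt((segs$e1 - segs$s1)^2 + (segs$e2 - segs$s2)^2 +
                 (segs$e3 - segs$s3)^2)
  expect_equal(sum(lens), 300, tolerance = 1e-9)
  dirs <- cbind(segs$e1 - segs$s1, segs$e2 - segs$s2, segs$e3 - segs$s3)
  dirs <- dirs / lens
  for (r in 2:5) expect_equal(dirs[r, ], dirs[1, ], tolerance = 1e-9)
})

test_that("degenerate spec (min_radius > root_radius) warns and returns no segments", {
  spec <- small_phantom_spec()
  spec$min_radius <- spec$root_radius + 1
  expect_warning(segs <- generate_vessel_tree(spec), "degenerate")
  expect_equal(nrow(segs), 0L)
})

test_that("analytic totals match an independent per-segment loop", {
  spec <- small_phantom_spec(lesion = FALSE, noise_sd = 0)
  segs <- generate_vessel_tree(spec)
  acc_len <- 0
  acc_vol <- 0
  for (r in seq_len(nrow(segs))) {
    l <- sqrt((segs$e1[r] - segs$s1[r])^2 + (segs$e2[r] - segs$s2[r])^2 +
                (segs$e3[r] - segs$s3[r])^2)
    acc_len <- acc_len + l
    acc_vol <- acc_vol + pi * segs$radius[r]^2 * l
  }
  ph <- rasterize_phantom(spec)
  expect_equal(ph$truth$total_vessel_length_mm, acc_len * 1e-3,
               tolerance = 1e-9)
  expect_equal(ph$truth$total_vessel_volume_mm3, acc_vol * 1e-9,
               tolerance = 1e-9)
})

test_that("per-depth-bin truth sums to the totals", {
  ph <- rasterize_phantom(small_phantom_spec())
  expect_equal(sum(ph$truth$vessel_by_depth$length_mm),
               ph$truth$total_vessel_length_mm, tolerance = 1e-6)
  expect_equal(sum(ph$truth$vessel_by_depth$volume_mm3),
               ph$truth$total_vessel_volume_mm3, tolerance = 1e-6)
})

test_that("rasterization is deterministic and noise-free channels are exact", {
  spec <- small_phantom_spec(noise_sd = 0, n_trees = 0L, lesion = FALSE)
  ph <- rasterize_phantom(spec)
  ph2 <- rasterize_phantom(spec)
  expect_identical(ph$extravasation$values, ph2$extravasation$values)

  # no vessels, no lesion, no noise: extravasation is exactly the
  # autofluorescence level inside tissue and 0 outside
  tis <- ph$tissue$values
  expect_true(all(ph$extravasation$values[tis] ==
                    spec$autofluorescence_level))
  expect_true(all(ph$extravasation$values[!tis] == 0))

  spec_n <- small_phantom_spec()
  pha <- rasterize_phantom(spec_n)
  phb <- rasterize_phantom(spec_n)
  expect_identical(pha$vessel$values, phb$vessel$values)
  expect_identical(pha$hypoxia$values, phb$hypoxia$values)
})

test_that("a single straight tube rasterizes to its analytic volume", {
  # one unbranched vertical branch: the rasterized voxel count should match
  # the analytic capsule-union volume pi r^2 L + 4/3 pi r^3 within 10%
  spec <- phantom_spec(brain_semi_axes = c(800, 500, 500), spacing = 10,
                       branching_depth = 0L, n_trees = 1L, root_radius = 40,
                       segments_per_branch = 4L, branch_length_um = 600,
                       lesion_center = NULL, noise_sd = 0, seed = 5L)
  ph <- rasterize_phantom(spec)
  segs <- ph$segments
  L <- sum(sqrt((segs$e1 - segs$s1)^2 + (segs$e2 - segs$s2)^2 +
                  (segs$e3 - segs$s3)^2))
  r <- segs$radius[1]
  analytic <- pi * r^2 * L + 4 / 3 * pi * r^3
  n_vox <- sum(ph$vessel$values > spec$autofluorescence_level +
                 spec$vessel_intensity / 2)
  expect_equal(n_vox * prod(spec$spacing), analytic, tolerance = 0.10)
})

test_that("truth lesion volume matches the rasterized cavity", {
  spec <- small_phantom_spec(noise_sd = 0, n_trees = 0L)
  ph <- rasterize_phantom(spec)
  # independent voxel-count oracle: brain ellipsoid minus returned tissue
  dims <- dim(ph$tissue$values)
  ctr_um <- ph$truth$brain_center_um
  idx <- which(array(TRUE, dims), arr.ind = TRUE)
  p <- sweep(sweep(idx, 2, c(1, 1, 1)) , 2, spec$spacing, "*")
  p <- sweep(p, 2, ctr_um)
  in_brain <- rowSums(sweep(p, 2, spec$brain_semi_axes, "/")^2) <= 1
  cavity <- sum(in_brain & !ph$tissue$values)
  expect_equal(ph$truth$lesion_volume_mm3,
               cavity * prod(spec$spacing) * 1e-9, tolerance = 0.05)
})

test_that("a lesion-free phantom is mirror-symmetric across the midplane", {
  spec <- small_phantom_spec(lesion = FALSE, n_trees = 0L, noise_sd = 0)
  ph <- rasterize_phantom(spec)
  tis <- ph$tissue$values
  flipped <- tis[, , rev(seq_len(dim(tis)[3]))]
  expect_identical(tis, flipped)
})

test_that("perilesional signal decays with depth", {
  spec <- small_phantom_spec(noise_sd = 0, n_trees = 0L)
  ph <- rasterize_phantom(spec)
  # reconstruct the cavity analytically to measure depth independently
  dims <- dim(ph$tissue$values)
  ctr_um <- ph$truth$brain_center_um
  idx <- which(array(TRUE, dims), arr.ind = TRUE)
  p <- sweep(sweep(idx, 2, c(1, 1, 1)), 2, spec$spacing, "*")
  p <- sweep(p, 2, ctr_um)
  lc <- spec$lesion_center
  inl <- rowSums(sweep(sweep(p, 2, lc), 2, spec$lesion_semi_axes, "/")^2) <= 1
  lesion <- array(FALSE, dims)
  lesion[idx[inl, , drop = FALSE]] <- TRUE
  d <- tbi3d:::distance_to_mask(binary_mask(lesion, spec$spacing))
  tis <- ph$tissue$values
  near <- tis & d > 0 & d < 100
  far <- tis & d >= 400 & d < 500
  expect_gt(mean(ph$hypoxia$values[near]), mean(ph$hypoxia$values[far]))
})

test_that("a lesion outside the tissue is rejected", {
  spec <- small_phantom_spec()
  spec$lesion_center <- c(-2000, 0, 2000)
  expect_error(rasterize_phantom(spec), "does not intersect")
  expect_error(phantom_spec(lesion_center = c(0, 0, -100)), "hemisphere")
})
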