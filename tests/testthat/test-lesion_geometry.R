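test_that("tissue segmentation separates autofluorescence from background", {
  g0 <- voxel_grid(array(0, c(8, 8, 8)), 10)
  expect_error(segment_tissue(g0, 10), "empty tissue")

  # perfect separation: threshold midway recovers the phantom tissue exactly
  spec <- small_phantom_spec(noise_sd = 0, n_trees = 0L)
  ph <- rasterize_phantom(spec)
  tis <- segment_tissue(ph$extravasation, 50)
  expect_identical(tis$values, ph$tissue$values)

  # with noise, auto (Otsu) threshold recovers tissue volume within 2%
  spec_n <- small_phantom_spec(noise_sd = 10, n_trees = 0L, signal_peak = 0)
  ph_n <- rasterize_phantom(spec_n)
  tis_n <- segment_tissue(ph_n$extravasation, "auto")
  expect_equal(mask_volume_mm3(tis_n), mask_volume_mm3(ph_n$tissue),
               tolerance = 0.02)
})

test_that("surface solidification is idempotent on convex solids and bridges cavities", {
  expect_error(solidify_surface(binary_mask(array(FALSE, c(8, 8, 8)), 10)),
               "empty")
  expect_error(solidify_surface(full_mask(c(8, 8, 8), 10), 1), "voxel")

  ell <- ellipsoid_mask(c(41, 41, 41), c(15, 17, 13), spacing = 10)
  out <- solidify_surface(ell, 80)
  jac <- sum(out$values & ell$values) / sum(out$values | ell$values)
  expect_gte(jac, 0.999)
  expect_true(all(out$values[ell$values])) # output contains input

  # a 6-voxel-wide surface notch is bridged by a wider closing ball
  box <- array(FALSE, c(30, 30, 30))
  box[5:26, 5:26, 5:26] <- TRUE
  notch <- array(FALSE, c(30, 30, 30))
  notch[5:12, 13:18, 13:18] <- TRUE # opens at the i=5 face, 60 um wide
  m <- binary_mask(box & !notch, 10)
  solid <- solidify_surface(m, 80)
  # interior notch voxels become solid (the exact mouth plane may stay on
  # the rolling-ball hull boundary)
  interior <- notch & box
  interior[5, , ] <- FALSE
  expect_true(all(solid$values[interior]))
  # and the complement has a single connected component (no internal holes)
  comp <- label_components(binary_mask(!solid$values, 10), 6)
  expect_equal(attr(comp, "ncomp"), 1L)
})

test_that("midsagittal plane is the center of mass along the left-right axis", {
  m <- array(FALSE, c(9, 9, 99))
  m[3:7, 3:7, 26:75] <- TRUE # symmetric about index 50.5
  pl <- find_midsagittal(binary_mask(m, 10), 3)
  expect_equal(pl$plane_position, 50.5)

  single <- array(FALSE, c(9, 9, 9))
  single[4, 5, 7] <- TRUE
  expect_equal(find_midsagittal(binary_mask(single, 10), 3)$plane_position, 7)

  # asymmetric two-blob mask vs a brute-force weighted mean of indices
  two <- array(FALSE, c(9, 9, 40))
  two[2:4, 2:4, 3:7] <- TRUE
  two[2:6, 2:6, 20:35] <- TRUE
  got <- find_midsagittal(binary_mask(two, 10), 3)$plane_position
  acc <- 0; n <- 0
  for (i in 1:9) for (j in 1:9) for (k in 1:40)
    if (two[i, j, k]) { acc <- acc + k; n <- n + 1 }
  expect_equal(got, acc / n, tolerance = 1e-12)

  expect_error(find_midsagittal(binary_mask(array(FALSE, c(4, 4, 4)), 1)),
               "empty")
})

test_that("mirror subtraction returns nothing for a symmetric brain", {
  spec <- small_phantom_spec(lesion = FALSE, n_trees = 0L, noise_sd = 0)
  ph <- rasterize_phantom(spec)
  tis <- segment_tissue(ph$extravasation, 50)
  solid <- solidify_surface(tis, 250)
  pl <- find_midsagittal(solid, 3)
  les <- mirror_subtract_lesion(solid, pl, 1L, tissue = tis)
  expect_equal(mask_volume_mm3(les), 0)
})

test_that("mirror subtraction recovers a carved cavity and respects sidedness", {
  spec <- small_phantom_spec(noise_sd = 10, n_trees = 0L, signal_peak = 0)
  ph <- rasterize_phantom(spec)
  tis <- segment_tissue(ph$extravasation, "auto")
  solid <- solidify_surface(tis, 250)
  pl <- find_midsagittal(solid, 3)
  les <- mirror_subtract_lesion(solid, pl, 1L, tissue = tis)
  expect_equal(mask_volume_mm3(les), ph$truth$lesion_volume_mm3,
               tolerance = 0.10)

  # looking for the lesion on the wrong side finds nothing
  les_wrong <- mirror_subtract_lesion(solid, pl, -1L, tissue = tis)
  expect_equal(mask_volume_mm3(les_wrong), 0)

  bad <- structure(list(axis = 3L, plane_position = 10000),
                   class = "midsagittal_plane")
  expect_error(mirror_subtract_lesion(solid, bad, 1L), "outside")
})

test_that("lesion volume is stable under whole-voxel translation", {
  spec <- small_phantom_spec(noise_sd = 0, n_trees = 0L)
  ph <- rasterize_phantom(spec)
  run <- function(tis_arr) {
    tis <- binary_mask(tis_arr, spec$spacing)
    solid <- solidify_surface(tis, 250)
    pl <- find_midsagittal(solid, 3)
    mask_volume_mm3(mirror_subtract_lesion(solid, pl, 1L, tissue = tis))
  }
  v0 <- run(ph$tissue$values)
  v1 <- run(tbi3d:::shift_array(ph$tissue$values, c(2L, -1L, 0L)))
  expect_equal(v1, v0, tolerance = 0.02)
})

test_that("lesion boundary matches a brute-force 6-adjacency scan", {
  d <- c(20, 20, 20)
  tissue_all <- array(TRUE, d)
  lesion <- array(FALSE, d)
  lesion[8:12, 8:12, 8:12] <- TRUE
  solid <- binary_mask(tissue_all, 10)
  bnd <- lesion_boundary(binary_mask(lesion, 10), solid)

  oracle <- array(FALSE, d)
  for (i in 1:20) for (j in 1:20) for (k in 1:20) {
    if (lesion[i, j, k]) next
    nb <- FALSE
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      p <- c(i, j, k) + o
      if (all(p >= 1 & p <= 20) && lesion[p[1], p[2], p[3]]) nb <- TRUE
    }
    oracle[i, j, k] <- nb
  }
  expect_identical(bnd$values, oracle)
  expect_equal(sum(bnd$values), sum(oracle))
})

test_that("boundary handles empty and total lesions", {
  d <- c(10, 10, 10)
  solid <- full_mask(d, 10)
  none <- empty_mask_like(solid)
  expect_equal(sum(lesion_boundary(none, solid)$values), 0)

  window <- binary_mask(array(c(TRUE, rep(FALSE, 999)), d), 10)
  expect_identical(lesion_boundary(none, solid, craniotomy_window = window),
                   window)

  all_lesion <- full_mask(d, 10)
  expect_equal(sum(lesion_boundary(all_lesion, solid)$values), 0)
})
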