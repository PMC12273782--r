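# Shared fixtures, generated in code.

# Desk-scale phantom: ~58 x 63 x 68 voxels at 12 um, one cortical-surface
# cavity in the x > 0 hemisphere, vessels thick enough (>= 2.5 voxels radius)
# for skeleton and Frangi analysis.
small_phantom_spec <- function(seed = 1L, noise_seed = seed + 1000L,
                               n_trees = 3L, lesion = TRUE, noise_sd = 20,
                               signal_peak = 300, ...) {
  phantom_spec(
    brain_semi_axes = c(300, 330, 360), spacing = c(12, 12, 12),
    root_radius = 30, branching_depth = 3L, branch_length_um = 200,
    min_radius = 14, n_trees = n_trees,
    lesion_center = if (lesion) c(-240, 0, 170) else NULL,
    lesion_semi_axes = c(150, 140, 130),
    signal_decay_length = 100, signal_peak_intensity = signal_peak,
    noise_sd = noise_sd, seed = seed, noise_seed = noise_seed, ...)
}

# axis-aligned solid cylinder along axis 1, flat ends
cylinder_mask <- function(len_vox, r_vox, spacing = 1, pad = 6) {
  d <- c(len_vox + 2 * pad, 2 * (r_vox + pad) + 1, 2 * (r_vox + pad) + 1)
  ctr <- r_vox + pad + 1
  m <- array(FALSE, d)
  g <- as.matrix(expand.grid(j = seq_len(d[2]), k = seq_len(d[3])))
  disk <- g[(g[, 1] - ctr)^2 + (g[, 2] - ctr)^2 <= r_vox^2, , drop = FALSE]
  for (i in pad + seq_len(len_vox)) m[cbind(i, disk)] <- TRUE
  binary_mask(m, rep(spacing, 3))
}

# solid cylinder at 45 degrees in the (1,2) plane
oblique_cylinder_mask <- function(axis_len_vox, r_vox, spacing = 1) {
  n <- axis_len_vox + 2 * (r_vox + 6)
  d <- c(n, n, 2 * (r_vox + 6) + 1)
  m <- array(FALSE, d)
  idx <- which(array(TRUE, d), arr.ind = TRUE)
  p0 <- c(r_vox + 6, r_vox + 6, r_vox + 7)
  u <- c(1, 1, 0) / sqrt(2)
  v <- sweep(idx, 2, p0)
  t <- as.numeric(v %*% u)
  perp2 <- rowSums((v - outer(t, u))^2)
  m[idx[perp2 <= r_vox^2 & t >= 0 & t <= axis_len_vox, , drop = FALSE]] <- TRUE
  binary_mask(m, rep(spacing, 3))
}

# ellipsoid tissue mask centered in the grid
ellipsoid_mask <- function(dims, semi_vox, spacing = 1) {
  ctr <- (dims + 1) / 2
  idx <- which(array(TRUE, dims), arr.ind = TRUE)
  inside <- rowSums(sweep(sweep(idx, 2, ctr), 2, semi_vox, "/")^2) <= 1
  m <- array(FALSE, dims)
  m[idx[inside, , drop = FALSE]] <- TRUE
  binary_mask(m, rep(spacing, 3))
}

empty_mask_like <- function(mask) {
  binary_mask(array(FALSE, dim(mask$values)), mask$spacing)
}

full_mask <- function(dims, spacing = 1) {
  binary_mask(array(TRUE, dims), rep(spacing, 3))
}
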