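#' Specification of a synthetic brain phantom
#'
#' Describes a bilaterally symmetric ellipsoidal "brain" with a branched
#' bright-tube vascular network, an optional unilateral lesion cavity opening
#' to the dorsal surface, perilesional hypoxia/extravasation signal decaying
#' exponentially with distance from the lesion surface, and noisy tissue
#' autofluorescence. Axis order is (z dorsoventral, y rostrocaudal,
#' x left-right); dorsal is the low-z face and the midsagittal plane splits
#' the x axis, with the ipsilateral (lesioned) hemisphere at x > 0.
#'
#' @param brain_semi_axes Ellipsoid semi-axes in um, (z, y, x).
#' @param spacing Per-axis voxel spacing in um.
#' @param root_radius Vessel root radius in um.
#' @param radius_decay Child/parent radius ratio per bifurcation, in (0, 1].
#' @param branch_angle_range Bifurcation deflection range in degrees.
#' @param min_radius Branch termination radius in um; defaults to 1.5x the
#'   largest voxel spacing.
#' @param segments_per_branch,branching_depth Tree shape integers.
#' @param branch_length_um Length of one straight branch in um.
#' @param n_trees Number of vessel trees seeded on the ventral surface.
#' @param lesion_center Cavity center as an offset from the brain center, um;
#'   `NULL` for no lesion. Must lie strictly in the x > 0 hemisphere.
#' @param lesion_semi_axes Cavity semi-axes in um.
#' @param signal_decay_length Exponential falloff length of the perilesional
#'   hypoxia/extravasation signal, um.
#' @param vessel_intensity,signal_peak_intensity,autofluorescence_level,noise_sd
#'   Intensity model parameters (arbitrary units).
#' @param seed Integer seed fixing the vessel tree geometry.
#' @param noise_seed Integer seed fixing the additive noise (defaults to
#'   `seed + 1000`), so cohorts can share geometry while varying noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(brain_semi_axes = c(500, 600, 650),
                         spacing = c(10, 10, 10),
                         root_radius = 30,
                         radius_decay = 0.75,
                         branch_angle_range = c(20, 60),
                         min_radius = NULL,
                         segments_per_branch = 4L,
                         branching_depth = 5L,
                         branch_length_um = 250,
                         n_trees = 4L,
                         lesion_center = c(-400, 0, 250),
                         lesion_semi_axes = c(250, 220, 200),
                         signal_decay_length = 150,
                         vessel_intensity = 400,
                         signal_peak_intensity = 300,
                         autofluorescence_level = 100,
                         noise_sd = 20,
                         seed = 1L,
                         noise_seed = NULL) {
  spacing <- if (length(spacing) == 1L) rep(spacing, 3L) else as.numeric(spacing)
  if (is.null(min_radius)) min_radius <- 1.5 * max(spacing)
  if (is.null(noise_seed)) noise_seed <- seed + 1000L
  spec <- list(
    brain_semi_axes = as.numeric(brain_semi_axes), spacing = spacing,
    root_radius = root_radius, radius_decay = radius_decay,
    branch_angle_range = as.numeric(branch_angle_range),
    min_radius = min_radius,
    segments_per_branch = as.integer(segments_per_branch),
    branching_depth = as.integer(branching_depth),
    branch_length_um = branch_length_um, n_trees = as.integer(n_trees),
    lesion_center = if (is.null(lesion_center)) NULL else as.numeric(lesion_center),
    lesion_semi_axes = as.numeric(lesion_semi_axes),
    signal_decay_length = signal_decay_length,
    vessel_intensity = vessel_intensity,
    signal_peak_intensity = signal_peak_intensity,
    autofluorescence_level = autofluorescence_level,
    noise_sd = noise_sd, seed = as.integer(seed),
    noise_seed = as.integer(noise_seed)
  )
  stopifnot(all(spec$brain_semi_axes > 0), all(spec$spacing > 0),
            spec$root_radius > 0, spec$min_radius > 0,
            spec$radius_decay > 0, spec$radius_decay <= 1,
            spec$segments_per_branch >= 1L, spec$branching_depth >= 0L,
            spec$branch_length_um > 0, spec$n_trees >= 0L,
            spec$signal_decay_length > 0)
  if (!is.null(spec$lesion_center)) {
    if (spec$lesion_center[3] <= 0)
      stop("lesion_center must lie strictly within the x > 0 hemisphere")
    stopifnot(all(spec$lesion_semi_axes > 0))
  }
  class(spec) <- "phantom_spec"
  spec
}

# evaluate RNG-dependent code under a seed without disturbing the caller's
# RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rotate_about <- function(v, axis, theta) {
  # Rodrigues rotation of v about unit axis by theta
  axis <- axis / sqrt(sum(axis^2))
  v * cos(theta) + pracma_cross(axis, v) * sin(theta) +
    axis * sum(axis * v) * (1 - cos(theta))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

random_perpendicular <- function(v) {
  repeat {
    r <- stats::rnorm(3)
    p <- r - v * sum(r * v) / sum(v * v)
    if (sqrt(sum(p^2)) > 1e-8) return(p / sqrt(sum(p^2)))
  }
}

inside_ellipsoid <- function(p, semi) sum((p / semi)^2) <= 1

#' Generate a recursive bifurcating vessel tree
#'
#' Trees are seeded on the ventral (high-z) brain surface and grow dorsally.
#' Each bifurcation multiplies the radius by `radius_decay` and deflects the
#' two children by an angle drawn uniformly from `branch_angle_range` about a
#' random axis perpendicular to the parent direction. Branches are straight
#' runs of `segments_per_branch` collinear segments and terminate when the
#' radius falls below `min_radius` or the branch exits the tissue ellipsoid.
#' Deterministic for a fixed seed.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A data.frame of tube segments with columns `s1,s2,s3` (start, um,
#'   relative to the brain center), `e1,e2,e3` (end), and `radius` (um).
#' @export
generate_vessel_tree <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  empty <- data.frame(s1 = numeric(), s2 = numeric(), s3 = numeric(),
                      e1 = numeric(), e2 = numeric(), e3 = numeric(),
                      radius = numeric())
  if (spec$min_radius > spec$root_radius) {
    warning("degenerate spec: min_radius exceeds root_radius; no vessels")
    return(empty)
  }
  if (spec$n_trees == 0L) return(empty)
  semi <- spec$brain_semi_axes
  seg_len <- spec$branch_length_um / spec$segments_per_branch
  rows <- list()

  grow <- function(start, dir, radius, depth) {
    pos <- start
    n_placed <- 0L
    for (s in seq_len(spec$segments_per_branch)) {
      nxt <- pos + dir * seg_len
      if (!inside_ellipsoid(nxt, semi)) break
      rows[[length(rows) + 1L]] <<- c(pos, nxt, radius)
      pos <- nxt
      n_placed <- n_placed + 1L
    }
    if (n_placed < spec$segments_per_branch) return(invisible(NULL))
    child_r <- radius * spec$radius_decay
    if (depth >= spec$branching_depth || child_r < spec$min_radius)
      return(invisible(NULL))
    axis <- random_perpendicular(dir)
    th <- stats::runif(2, spec$branch_angle_range[1],
                       spec$branch_angle_range[2]) * pi / 180
    d1 <- rotate_about(dir, axis, th[1])
    d2 <- rotate_about(dir, axis, -th[2])
    grow(pos, d1 / sqrt(sum(d1^2)), child_r, depth + 1L)
    grow(pos, d2 / sqrt(sum(d2^2)), child_r, depth + 1L)
  }

  with_seed(seed, {
    for (t in seq_len(spec$n_trees)) {
      # root on the ventral surface: draw (y, x) inside the 60% ellipse and
      # drop onto the z > 0 surface
      repeat {
        fy <- stats::runif(1, -0.6, 0.6)
        fx <- stats::runif(1, -0.6, 0.6)
        if (fy^2 + fx^2 < 0.36) break
      }
      y0 <- fy * semi[2]
      x0 <- fx * semi[3]
      z0 <- semi[1] * sqrt(max(0, 1 - (y0 / semi[2])^2 - (x0 / semi[3])^2))
      start <- c(z0 * 0.98, y0, x0)
      dir <- c(-1, stats::runif(1, -0.3, 0.3), stats::runif(1, -0.3, 0.3))
      dir <- dir / sqrt(sum(dir^2))
      grow(start, dir, spec$root_radius, 0L)
    }
  })
  if (length(rows) == 0L) return(empty)
  m <- do.call(rbind, rows)
  stats::setNames(as.data.frame(m), c("s1", "s2", "s3", "e1", "e2", "e3", "radius"))
}

segment_lengths <- function(segments) {
  sqrt((segments$e1 - segments$s1)^2 + (segments$e2 - segments$s2)^2 +
       (segments$e3 - segments$s3)^2)
}

# distance from point p (centered coordinates) to the surface of an
# axis-aligned ellipsoid with semi-axes a, via the Lagrange parameter root of
# sum((a_i p_i / (t + a_i^2))^2) = 1
dist_point_ellipsoid <- function(p, a) {
  if (all(abs(p) < 1e-12)) return(min(a))
  f <- function(t) sum((a * p / (t + a^2))^2) - 1
  lo <- -min(a^2) + 1e-9
  hi <- max(sum(abs(a * p)), max(a)^2)
  while (f(hi) > 0) hi <- hi * 2
  t0 <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  x <- a^2 * p / (t0 + a^2)
  sqrt(sum((x - p)^2))
}

#' Rasterize a phantom brain onto voxel grids
#'
#' Produces the three fluorescence channels, the noise-free tissue mask, and
#' a ground-truth record. Tissue voxels carry `autofluorescence_level`;
#' vessel voxels additionally carry `vessel_intensity` in the vessel channel;
#' hypoxia/extravasation channels add
#' `signal_peak_intensity * exp(-d / signal_decay_length)` at distance `d`
#' from the lesion surface, zeroed in the contralateral hemisphere beyond
#' three decay lengths; lesion-cavity voxels are background in all channels
#' and removed from tissue. Gaussian noise of sd `noise_sd` is added
#' everywhere (seeded by `spec$noise_seed`).
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `vessel`, `extravasation`, `hypoxia`
#'   ([voxel_grid()]s), `tissue` ([binary_mask()], lesion carved out),
#'   `segments` (the vessel tube table), and `truth` (a list with
#'   `lesion_volume_mm3`, `total_vessel_length_mm`, `total_vessel_volume_mm3`,
#'   `vessel_by_depth` (per-100-um-bin analytic length/volume),
#'   `signal_volume_mm3`, and `brain_center_um`).
#' @export
rasterize_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  semi <- spec$brain_semi_axes
  pad <- 4L
  dims <- as.integer(ceiling(2 * semi / spec$spacing) + 2L * pad)
  center <- (dims + 1) / 2 # voxel index of the brain center
  center_um <- (center - 1) * spec$spacing

  ax <- lapply(1:3, function(a) ((seq_len(dims[a]) - 1) * spec$spacing[a]) - center_um[a])
  # squared normalized radius field of the brain ellipsoid
  r2 <- outer(outer((ax[[1]] / semi[1])^2, (ax[[2]] / semi[2])^2, "+"),
              (ax[[3]] / semi[3])^2, "+")
  brain <- r2 <= 1

  lesion <- array(FALSE, dims)
  if (!is.null(spec$lesion_center)) {
    lc <- spec$lesion_center
    ls <- spec$lesion_semi_axes
    l2 <- outer(outer(((ax[[1]] - lc[1]) / ls[1])^2,
                      ((ax[[2]] - lc[2]) / ls[2])^2, "+"),
                ((ax[[3]] - lc[3]) / ls[3])^2, "+")
    lesion <- l2 <= 1
    if (!any(lesion & brain))
      stop("configured lesion does not intersect the tissue ellipsoid")
  }
  tissue <- brain & !lesion
  tissue_mask <- binary_mask(tissue, spec$spacing, "tissue")

  segments <- generate_vessel_tree(spec)
  vessel_mask <- array(FALSE, dims)
  if (nrow(segments) > 0) {
    origin0 <- -center_um # physical coordinate of voxel index 1 (centered frame)
    vm <- rasterize_tubes_cpp(
      as.matrix(segments[, c("s1", "s2", "s3")]),
      as.matrix(segments[, c("e1", "e2", "e3")]),
      segments$radius, dims, spec$spacing, origin0)
    vessel_mask <- array(vm, dims) & tissue
  }

  auto <- spec$autofluorescence_level
  vessel_ch <- array(0, dims)
  vessel_ch[tissue] <- auto
  vessel_ch[vessel_mask] <- auto + spec$vessel_intensity

  signal_det <- array(0, dims)
  lesion_any <- any(lesion)
  if (lesion_any) {
    dmap <- distance_to_mask(binary_mask(lesion, spec$spacing, "lesion"))
    sig <- spec$signal_peak_intensity * exp(-dmap / spec$signal_decay_length)
    contra <- outer(outer(rep(TRUE, dims[1]), rep(TRUE, dims[2]), "&"),
                    ax[[3]] < 0, "&")
    sig[contra & dmap > 3 * spec$signal_decay_length] <- 0
    sig[!tissue] <- 0
    signal_det <- sig
  }
  extrav_ch <- array(0, dims)
  extrav_ch[tissue] <- auto
  extrav_ch <- extrav_ch + signal_det
  hypox_ch <- array(0, dims)
  hypox_ch[tissue] <- auto
  hypox_ch <- hypox_ch + signal_det

  if (spec$noise_sd > 0) {
    with_seed(spec$noise_seed, {
      vessel_ch <- vessel_ch + stats::rnorm(length(vessel_ch), 0, spec$noise_sd)
      extrav_ch <- extrav_ch + stats::rnorm(length(extrav_ch), 0, spec$noise_sd)
      hypox_ch <- hypox_ch + stats::rnorm(length(hypox_ch), 0, spec$noise_sd)
    })
    dim(vessel_ch) <- dims; dim(extrav_ch) <- dims; dim(hypox_ch) <- dims
  }

  truth <- phantom_truth(spec, segments, signal_det, tissue, lesion, ax)
  truth$brain_center_um <- center_um

  list(
    vessel = voxel_grid(vessel_ch, spec$spacing, "vessel"),
    extravasation = voxel_grid(extrav_ch, spec$spacing, "extravasation"),
    hypoxia = voxel_grid(hypox_ch, spec$spacing, "hypoxia"),
    tissue = tissue_mask,
    segments = segments,
    truth = truth
  )
}

# Ground truth computed independently of the measurement pipeline: lesion
# volume by refined rasterization, vessel totals and 100-um depth bins from
# the analytic segment list (segment-midpoint binning, whole segments), and
# the supra-background signal volume from the deterministic signal field.
phantom_truth <- function(spec, segments, signal_det, tissue, lesion, ax) {
  semi <- spec$brain_semi_axes
  vox_mm3 <- prod(spec$spacing) * 1e-9

  lesion_volume_mm3 <- 0
  if (!is.null(spec$lesion_center)) {
    # refine on a 2x finer grid over the lesion bounding box
    lc <- spec$lesion_center
    ls <- spec$lesion_semi_axes
    h <- spec$spacing / 2
    axf <- lapply(1:3, function(a)
      seq(lc[a] - ls[a] - h[a], lc[a] + ls[a] + h[a], by = h[a]))
    inl <- outer(outer(((axf[[1]] - lc[1]) / ls[1])^2,
                       ((axf[[2]] - lc[2]) / ls[2])^2, "+"),
                 ((axf[[3]] - lc[3]) / ls[3])^2, "+") <= 1
    inb <- outer(outer((axf[[1]] / semi[1])^2, (axf[[2]] / semi[2])^2, "+"),
                 (axf[[3]] / semi[3])^2, "+") <= 1
    lesion_volume_mm3 <- sum(inl & inb) * prod(h) * 1e-9
  }

  tot_len_mm <- 0
  tot_vol_mm3 <- 0
  by_depth <- data.frame(d_min = numeric(), d_max = numeric(),
                         length_mm = numeric(), volume_mm3 = numeric())
  if (nrow(segments) > 0) {
    mid <- cbind((segments$s1 + segments$e1) / 2,
                 (segments$s2 + segments$e2) / 2,
                 (segments$s3 + segments$e3) / 2)
    keep <- rep(TRUE, nrow(segments))
    depth <- rep(NA_real_, nrow(segments))
    if (!is.null(spec$lesion_center)) {
      lc <- spec$lesion_center
      ls <- spec$lesion_semi_axes
      inside <- rowSums(sweep(sweep(mid, 2, lc), 2, ls, "/")^2) <= 1
      keep <- !inside
      depth[keep] <- vapply(which(keep), function(i)
        dist_point_ellipsoid(mid[i, ] - lc, ls), numeric(1))
    } else {
      depth[] <- Inf
    }
    len <- segment_lengths(segments)
    vol <- pi * segments$radius^2 * len
    tot_len_mm <- sum(len[keep]) * 1e-3
    tot_vol_mm3 <- sum(vol[keep]) * 1e-9
    if (any(keep) && any(is.finite(depth[keep]))) {
      bin <- floor(depth[keep] / 100)
      by_depth <- data.frame(
        d_min = sort(unique(bin)) * 100,
        d_max = (sort(unique(bin)) + 1) * 100,
        length_mm = as.numeric(tapply(len[keep] * 1e-3, bin, sum)),
        volume_mm3 = as.numeric(tapply(vol[keep] * 1e-9, bin, sum))
      )
    }
  }

  thr <- if (spec$noise_sd > 0) 3.0902 * spec$noise_sd else 0
  signal_volume_mm3 <- sum(signal_det > thr & tissue) * vox_mm3

  list(lesion_volume_mm3 = lesion_volume_mm3,
       total_vessel_length_mm = tot_len_mm,
       total_vessel_volume_mm3 = tot_vol_mm3,
       vessel_by_depth = by_depth,
       signal_volume_mm3 = signal_volume_mm3)
}
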