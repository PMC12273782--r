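#' Frangi vesselness parameters
#'
#' @param scales_um Gaussian scales sigma in um (default 3, 6, 12, 24),
#'   spanning the expected vessel radii.
#' @param alpha Plate/line discriminator weight (default 0.5).
#' @param beta Blob discriminator weight (default 0.5).
#' @param c Structureness weight; `NULL` (default) uses half the maximum
#'   Hessian Frobenius norm over the volume at each scale.
#' @param bright_tubes `TRUE` for bright vessels on dark background.
#' @return An object of class `vesselness_params`.
#' @export
vesselness_params <- function(scales_um = c(3, 6, 12, 24), alpha = 0.5,
                              beta = 0.5, c = NULL, bright_tubes = TRUE) {
  stopifnot(length(scales_um) >= 1, all(scales_um > 0), alpha > 0, beta > 0,
            is.null(c) || c > 0)
  structure(list(scales_um = as.numeric(scales_um), alpha = alpha, beta = beta,
                 c = c, bright_tubes = isTRUE(bright_tubes)),
            class = "vesselness_params")
}

#' Multi-scale Frangi vesselness filter
#'
#' For each scale sigma the volume is smoothed by a Gaussian of that physical
#' width and the gamma=1 scale-normalized Hessian (second derivatives times
#' sigma^2) is diagonalized per voxel. With eigenvalues ordered
#' |l1| <= |l2| <= |l3|, the geometric ratios R_A = |l2|/|l3| (plate vs
#' line), R_B = |l1|/sqrt(|l2 l3|) (blob), and the structureness
#' S = sqrt(l1^2 + l2^2 + l3^2) combine into
#' `V = (1 - exp(-R_A^2/2a^2)) * exp(-R_B^2/2b^2) * (1 - exp(-S^2/2c^2))`
#' wherever l2, l3 < 0 (bright tubes), else 0. The response is the maximum
#' over scales and lies in `[0, 1]`.
#'
#' @param grid Intensity [voxel_grid()] (at least 3 voxels per axis).
#' @param params A [vesselness_params()].
#' @return A [voxel_grid()] of vesselness in `[0, 1]`.
#' @export
frangi_vesselness <- function(grid, params = vesselness_params()) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(params, "vesselness_params"))
  if (any(dim(grid$values) < 3L))
    stop("Hessian undefined: need at least 3 voxels per axis")
  d <- dim(grid$values)
  out <- array(0, d)
  for (s in params$scales_um) {
    v <- frangi_scale_cpp(as.numeric(grid$values), d, grid$spacing, s,
                          params$alpha, params$beta,
                          if (is.null(params$c)) -1 else params$c,
                          params$bright_tubes)
    out <- pmax(out, array(v, d))
  }
  voxel_grid(out, grid$spacing, "vesselness", grid$origin)
}

#' Threshold a vesselness map into a vessel mask
#'
#' @param vesselness Vesselness [voxel_grid()] from [frangi_vesselness()].
#' @param threshold Value in (0, 1).
#' @param min_component_mm3 Components smaller than this are removed.
#' @return A `binary_mask` of vessels.
#' @export
segment_vessels <- function(vesselness, threshold = 0.2,
                            min_component_mm3 = 1e-5) {
  stopifnot(inherits(vesselness, "voxel_grid"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly in (0, 1)")
  m <- binary_mask(vesselness$values > threshold, vesselness$spacing,
                   "vessel", vesselness$origin)
  filter_small_components(m, min_component_mm3)
}

#' Extract the vessel centerline graph
#'
#' Topological thinning to a 1-voxel-wide centerline, graph construction on
#' 26-connectivity, per-node radius from the Euclidean distance transform of
#' the vessel mask evaluated at the centerline, and physical edge lengths
#' from the voxel step.
#'
#' @param mask Vessel `binary_mask`.
#' @return An object of class `skeleton_graph`: `nodes` data.frame
#'   (`i, j, k` voxel indices, `radius_um`, `degree`), `edges` data.frame
#'   (`from, to` node row indices, `length_um`), plus `spacing`, `dim`.
#'   An empty mask yields an empty graph.
#' @export
skeletonize_vessels <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$values)
  sp <- mask$spacing
  if (!any(mask$values)) {
    return(structure(list(
      nodes = data.frame(i = integer(), j = integer(), k = integer(),
                         radius_um = numeric(), degree = integer()),
      edges = data.frame(from = integer(), to = integer(),
                         length_um = numeric()),
      spacing = sp, dim = d), class = "skeleton_graph"))
  }
  skel <- skeletonize_cpp(as.logical(mask$values), d)
  dim(skel) <- d
  radius <- edt_cpp(as.logical(mask$values), d, sp)
  dim(radius) <- d

  idx <- which(skel)
  coords <- which(skel, arr.ind = TRUE)
  node_id <- array(0L, d)
  node_id[idx] <- seq_along(idx)

  # half of the 26-neighborhood, so each unordered pair appears once
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
           (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  from <- integer()
  to <- integer()
  len <- numeric()
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    ni <- coords[, 1] + o[1]
    nj <- coords[, 2] + o[2]
    nk <- coords[, 3] + o[3]
    ok <- ni >= 1 & nj >= 1 & nk >= 1 & ni <= d[1] & nj <= d[2] & nk <= d[3]
    if (!any(ok)) next
    nb <- node_id[cbind(ni[ok], nj[ok], nk[ok])]
    hit <- nb > 0
    if (!any(hit)) next
    from <- c(from, which(ok)[hit])
    to <- c(to, nb[hit])
    len <- c(len, rep(sqrt(sum((o * sp)^2)), sum(hit)))
  }
  deg <- tabulate(c(from, to), nbins = length(idx))
  structure(list(
    nodes = data.frame(i = coords[, 1], j = coords[, 2], k = coords[, 3],
                       radius_um = radius[idx], degree = deg),
    edges = data.frame(from = from, to = to, length_um = len),
    spacing = sp, dim = d), class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf(
    "<skeleton_graph> %d nodes, %d edges, total length %.3f mm\n",
    nrow(x$nodes), nrow(x$edges), sum(x$edges$length_um) * 1e-3))
  invisible(x)
}

#' Total centerline length of a skeleton graph, in mm
#' @param skeleton A `skeleton_graph`.
#' @export
skeleton_total_length_mm <- function(skeleton) {
  sum(skeleton$edges$length_um) * 1e-3
}

# per-edge mean radius; a branch node (degree >= 3) passes the other
# endpoint's radius instead of its own (the EDT overestimates at junctions)
edge_radii <- function(skeleton) {
  n <- skeleton$nodes
  e <- skeleton$edges
  rf <- n$radius_um[e$from]
  rt <- n$radius_um[e$to]
  bf <- n$degree[e$from] >= 3L
  bt <- n$degree[e$to] >= 3L
  rf2 <- ifelse(bf & !bt, rt, rf)
  rt2 <- ifelse(bt & !bf, rf, rt)
  (rf2 + rt2) / 2
}

#' Per-layer vessel length density and volume fraction
#'
#' Each skeleton edge is assigned to the depth layer containing its midpoint.
#' Layer vessel length is the sum of edge lengths (mm); layer vessel volume
#' is the frustum/cylinder sum `pi * rbar^2 * l` over edges (mm^3), with
#' `rbar` the mean of the two node radii (branch-point radii substituted by
#' the non-branch neighbor). Both are normalized by the layer's tissue
#' volume. Layers with vessel content but zero tissue volume report `NA`
#' with a warning.
#'
#' @param skeleton A `skeleton_graph`.
#' @param layers A `depth_layer_set` on the same physical frame.
#' @return data.frame with columns `d_min_um`, `d_max_um`, `length_mm`,
#'   `volume_mm3`, `tissue_volume_mm3`, `length_density_mm_per_mm3`,
#'   `volume_fraction`.
#' @export
vessel_metrics_per_layer <- function(skeleton, layers) {
  stopifnot(inherits(skeleton, "skeleton_graph"),
            inherits(layers, "depth_layer_set"))
  nl <- length(layers$layers)
  len_mm <- rep(0, nl)
  vol_mm3 <- rep(0, nl)
  if (nrow(skeleton$edges) > 0) {
    n <- skeleton$nodes
    e <- skeleton$edges
    mi <- pmin(pmax(round((n$i[e$from] + n$i[e$to]) / 2), 1), skeleton$dim[1])
    mj <- pmin(pmax(round((n$j[e$from] + n$j[e$to]) / 2), 1), skeleton$dim[2])
    mk <- pmin(pmax(round((n$k[e$from] + n$k[e$to]) / 2), 1), skeleton$dim[3])
    id <- layer_id_array(layers)
    lay <- id[cbind(mi, mj, mk)]
    rbar <- edge_radii(skeleton)
    evol <- pi * rbar^2 * e$length_um # um^3
    for (k in seq_len(nl)) {
      sel <- lay == k
      len_mm[k] <- sum(e$length_um[sel]) * 1e-3
      vol_mm3[k] <- sum(evol[sel]) * 1e-9
    }
  }
  tv <- layers$tissue_volumes_mm3
  dens <- ifelse(tv > 0, len_mm / tv, ifelse(len_mm > 0, NA_real_, 0))
  frac <- ifelse(tv > 0, vol_mm3 / tv, ifelse(vol_mm3 > 0, NA_real_, 0))
  if (anyNA(dens) || anyNA(frac))
    warning("layer with vessel content but zero tissue volume: metric is NA")
  data.frame(d_min_um = layers$d_min, d_max_um = layers$d_max,
             length_mm = len_mm, volume_mm3 = vol_mm3,
             tissue_volume_mm3 = tv,
             length_density_mm_per_mm3 = dens,
             volume_fraction = frac)
}
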