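#' Segment brain tissue from the autofluorescence channel
#'
#' Thresholds the extravasation/autofluorescence channel to separate tissue
#' from camera background and keeps the largest connected component.
#'
#' @param grid The extravasation/autofluorescence [voxel_grid()].
#' @param threshold Numeric intensity, or `"auto"` to select the threshold by
#'   Otsu's method on the intensity histogram.
#' @return A `binary_mask` of tissue.
#' @export
segment_tissue <- function(grid, threshold = "auto") {
  stopifnot(inherits(grid, "voxel_grid"))
  if (identical(threshold, "auto")) threshold <- otsu_threshold(grid$values)
  m <- grid$values > threshold
  if (!any(m))
    stop("empty tissue mask: threshold ", format(threshold),
         " is above the maximum intensity")
  largest_component(binary_mask(m, grid$spacing, "tissue", grid$origin))
}

# Otsu's method on a 256-bin histogram: threshold maximizing between-class
# variance, returned as the bin midpoint.
otsu_threshold <- function(values, nbins = 256L) {
  v <- as.numeric(values)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  sb <- (mu_t * w0 - mu)^2 / (w0 * w1)
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

#' Solidify the brain surface
#'
#' Morphological closing with a ball of physical radius followed by hole
#' filling. When the closing radius exceeds the half-width of the lesion
#' cavity's mouth, the mouth is bridged and the cavity becomes part of the
#' solid envelope — the raster analogue of surface shrink-wrap solidification.
#'
#' @param tissue A nonempty tissue `binary_mask`.
#' @param closing_radius_um Ball radius in um (default 300).
#' @return A `binary_mask` that is a superset of the input with no internal
#'   cavities.
#' @export
solidify_surface <- function(tissue, closing_radius_um = 300) {
  stopifnot(inherits(tissue, "binary_mask"))
  if (!any(tissue$values)) stop("cannot solidify an empty tissue mask")
  if (closing_radius_um < min(tissue$spacing))
    stop("closing radius is smaller than one voxel")
  out <- close_ball(tissue, closing_radius_um)
  out$values <- out$values | tissue$values # closing is extensive; be explicit
  fill_holes(out)
}

#' Midsagittal plane from the brain's center of mass
#'
#' @param solid A nonempty solidified brain `binary_mask`.
#' @param lr_axis Index (1-3) of the left-right grid axis.
#' @return A list with `axis` and `plane_position` (fractional 1-based index
#'   along that axis), class `midsagittal_plane`.
#' @export
find_midsagittal <- function(solid, lr_axis = 3L) {
  stopifnot(inherits(solid, "binary_mask"), lr_axis %in% 1:3)
  if (!any(solid$values)) stop("empty mask has no center of mass")
  idx <- which(solid$values, arr.ind = TRUE)
  structure(list(axis = as.integer(lr_axis),
                 plane_position = mean(idx[, lr_axis])),
            class = "midsagittal_plane")
}

# integer-shift a 3D logical array, zero (FALSE) fill
shift_array <- function(arr, shift) {
  d <- dim(arr)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    s <- shift[a]
    if (abs(s) >= d[a]) return(out)
    if (s >= 0) {
      dst[[a]] <- (1 + s):d[a]
      src[[a]] <- 1:(d[a] - s)
    } else {
      dst[[a]] <- 1:(d[a] + s)
      src[[a]] <- (1 - s):d[a]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# best integer translation of B maximizing overlap with A, searched within
# +/- max_shift voxels per axis via FFT cross-correlation
best_translation <- function(A, B, max_shift = 10L) {
  d <- dim(A)
  cc <- Re(stats::fft(stats::fft(A * 1) * Conj(stats::fft(B * 1)),
                      inverse = TRUE)) / prod(d)
  shifts <- lapply(d, function(n) {
    s <- c(0:min(max_shift, n - 1), if (max_shift > 0) -(1:min(max_shift, n - 1)))
    unique(s)
  })
  # index of shift s along axis of length n is (s mod n) + 1
  best <- c(0L, 0L, 0L)
  bestv <- -Inf
  for (s1 in shifts[[1]]) for (s2 in shifts[[2]]) for (s3 in shifts[[3]]) {
    v <- cc[(s1 %% d[1]) + 1, (s2 %% d[2]) + 1, (s3 %% d[3]) + 1]
    if (v > bestv) {
      bestv <- v
      best <- c(s1, s2, s3)
    }
  }
  best
}

#' Lesion mask by mirrored-hemisphere subtraction
#'
#' Reflects the brain across the midsagittal plane (so the uninjured
#' contralateral hemisphere lands on the injured side), rigidly aligns the
#' mirror to the original by the translation maximizing mask overlap, and
#' takes mirrored-minus-original restricted to the ipsilateral side. Small
#' components are removed as the automated stand-in for manual mask
#' refinement.
#'
#' @param solid Solidified brain `binary_mask`.
#' @param plane A `midsagittal_plane` from [find_midsagittal()] on the same
#'   mask.
#' @param ipsilateral_side `+1` if the injured hemisphere is at indices above
#'   `plane_position`, `-1` below.
#' @param search_voxels Translation search radius (voxels per axis).
#' @param min_component_mm3 Minimum retained lesion component volume.
#' @param tissue The tissue mask actually subtracted (mirrored contralateral
#'   tissue minus ipsilateral tissue). Defaults to `solid`; pass the
#'   unsolidified tissue mask when the solid envelope has the cavity filled,
#'   since missing tissue can only be detected against the true tissue map.
#' @return A `binary_mask` of the lesion.
#' @export
mirror_subtract_lesion <- function(solid, plane, ipsilateral_side = 1L,
                                   search_voxels = 10L,
                                   min_component_mm3 = 1e-3,
                                   tissue = solid) {
  stopifnot(inherits(solid, "binary_mask"),
            inherits(plane, "midsagittal_plane"),
            inherits(tissue, "binary_mask"),
            ipsilateral_side %in% c(-1L, 1L))
  stop_if_frame_mismatch(solid, tissue)
  d <- dim(solid$values)
  a <- plane$axis
  if (plane$plane_position < 1 || plane$plane_position > d[a])
    stop("plane position lies outside the grid")

  # reflect across the fractional plane: index j maps to round(2c - j)
  jsrc <- round(2 * plane$plane_position - seq_len(d[a]))
  ok <- jsrc >= 1 & jsrc <= d[a]
  mir <- array(FALSE, d)
  idx_dst <- idx_src <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  idx_dst[[a]] <- which(ok)
  idx_src[[a]] <- jsrc[ok]
  mir <- do.call(`[<-`, c(list(mir), idx_dst,
                          list(do.call(`[`, c(list(tissue$values), idx_src)))))

  shift <- best_translation(tissue$values, mir, as.integer(search_voxels))
  mir <- shift_array(mir, shift)

  ipsi <- if (ipsilateral_side > 0) {
    seq_len(d[a]) > plane$plane_position
  } else {
    seq_len(d[a]) < plane$plane_position
  }
  side <- array(FALSE, d)
  idx_side <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  idx_side[[a]] <- which(ipsi)
  side <- do.call(`[<-`, c(list(side), idx_side, list(TRUE)))

  # the mirrored tissue itself bounds the lesion region: anything outside
  # the (mirrored) brain cannot be called lost tissue
  lesion <- mir & !tissue$values & side
  filter_small_components(
    binary_mask(lesion, solid$spacing, "lesion", solid$origin),
    min_component_mm3)
}

# union of the six face-shifted copies of a logical array
adjacent6 <- function(arr) {
  out <- array(FALSE, dim(arr))
  for (a in 1:3) for (s in c(-1L, 1L)) {
    sh <- c(0L, 0L, 0L)
    sh[a] <- s
    out <- out | shift_array(arr, sh)
  }
  out
}

#' Tissue surface bounding the lesion
#'
#' The seed surface for depth layering: tissue voxels 6-adjacent to the
#' lesion mask, or to the exterior region where the lesion opens to the brain
#' surface. For an empty lesion (sham animals) an optional craniotomy-window
#' surface seed can be supplied; otherwise the boundary is empty.
#'
#' @param lesion Lesion `binary_mask`.
#' @param solid Solidified brain `binary_mask` on the same grid.
#' @param craniotomy_window Optional `binary_mask` returned as the seed when
#'   the lesion is empty.
#' @return A `binary_mask` of boundary voxels.
#' @export
lesion_boundary <- function(lesion, solid, craniotomy_window = NULL) {
  stopifnot(inherits(lesion, "binary_mask"), inherits(solid, "binary_mask"))
  stop_if_frame_mismatch(lesion, solid)
  if (!any(lesion$values)) {
    if (!is.null(craniotomy_window)) return(craniotomy_window)
    return(binary_mask(array(FALSE, dim(lesion$values)), lesion$spacing,
                       "boundary", lesion$origin))
  }
  tissue <- solid$values & !lesion$values
  exterior <- !solid$values
  opening <- exterior & adjacent6(lesion$values)
  seed <- lesion$values | opening
  boundary <- tissue & adjacent6(seed)
  binary_mask(boundary, lesion$spacing, "boundary", lesion$origin)
}
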