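#' Euclidean distance transform of a mask
#'
#' Exact anisotropic distance, in micrometers, from every voxel to the
#' nearest background (`FALSE`) voxel. Background voxels get 0; an all-true
#' mask returns `Inf` everywhere.
#'
#' @param mask A `binary_mask`.
#' @return A `voxel_grid` of distances (um).
#' @export
distance_transform <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- edt_cpp(as.logical(mask$values), dim(mask$values), mask$spacing)
  dim(d) <- dim(mask$values)
  voxel_grid(d, mask$spacing, paste0(mask$channel, ".edt"), mask$origin)
}

# distance (um) from every voxel to the nearest TRUE voxel of `mask`
distance_to_mask <- function(mask) {
  d <- edt_cpp(!as.logical(mask$values), dim(mask$values), mask$spacing)
  dim(d) <- dim(mask$values)
  d
}

#' Binary dilation / erosion with a physical-radius ball
#'
#' The structuring element is the set of voxels whose centers lie within
#' `radius_um` (ties at exactly the radius included); implemented through the
#' exact Euclidean distance transform, so it is anisotropy-aware.
#'
#' @param mask A `binary_mask`.
#' @param radius_um Ball radius in um (must cover at least one voxel step).
#' @return A `binary_mask`.
#' @export
dilate_ball <- function(mask, radius_um) {
  stopifnot(inherits(mask, "binary_mask"))
  if (radius_um < min(mask$spacing))
    stop("radius smaller than one voxel: nothing to dilate")
  out <- distance_to_mask(mask) <= radius_um
  binary_mask(out, mask$spacing, mask$channel, mask$origin)
}

#' @rdname dilate_ball
#' @export
erode_ball <- function(mask, radius_um) {
  stopifnot(inherits(mask, "binary_mask"))
  if (radius_um < min(mask$spacing))
    stop("radius smaller than one voxel: nothing to erode")
  d <- edt_cpp(as.logical(mask$values), dim(mask$values), mask$spacing)
  dim(d) <- dim(mask$values)
  binary_mask(d > radius_um, mask$spacing, mask$channel, mask$origin)
}

#' Morphological closing with a ball of physical radius
#'
#' The mask is zero-padded by the ball radius before dilating so the dilation
#' is never clipped at the array border (clipping would make the closing
#' either non-extensive or border-sticky); the result is cropped back.
#' Closing is exactly idempotent on convex rasters given this padding.
#'
#' @inheritParams dilate_ball
#' @export
close_ball <- function(mask, radius_um) {
  d <- dim(mask$values)
  pad <- as.integer(ceiling(radius_um / mask$spacing)) + 1L
  big <- array(FALSE, d + 2L * pad)
  big[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]),
      pad[3] + seq_len(d[3])] <- mask$values
  bm <- binary_mask(big, mask$spacing, mask$channel)
  closed <- erode_ball(dilate_ball(bm, radius_um), radius_um)
  out <- closed$values[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]),
                       pad[3] + seq_len(d[3])]
  binary_mask(out, mask$spacing, mask$channel, mask$origin)
}

#' Fill internal cavities of a mask
#'
#' Background 6-components that do not touch the array border are holes and
#' are added to the mask.
#'
#' @param mask A `binary_mask`.
#' @return A `binary_mask` with no internal cavities.
#' @export
fill_holes <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  bg <- !mask$values
  lab <- label_components_cpp(as.logical(bg), dim(bg), 6L)
  dim(lab) <- dim(bg)
  border_labels <- unique(c(
    lab[1, , ], lab[dim(lab)[1], , ],
    lab[, 1, ], lab[, dim(lab)[2], ],
    lab[, , 1], lab[, , dim(lab)[3]]
  ))
  border_labels <- border_labels[border_labels > 0]
  out <- mask$values | (lab > 0 & !(lab %in% border_labels))
  binary_mask(out, mask$spacing, mask$channel, mask$origin)
}

#' Label connected components of a mask
#'
#' @param mask A `binary_mask`.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return Integer array of labels (0 = background) with attribute `ncomp`.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "binary_mask"), connectivity %in% c(6L, 26L))
  lab <- label_components_cpp(as.logical(mask$values), dim(mask$values),
                              as.integer(connectivity))
  nc <- attr(lab, "ncomp")
  dim(lab) <- dim(mask$values)
  attr(lab, "ncomp") <- nc
  lab
}

#' Drop connected components below a physical size
#'
#' @param mask A `binary_mask`.
#' @param min_mm3 Minimum component volume in mm^3; smaller components are
#'   removed.
#' @param connectivity Passed to [label_components()].
#' @return A `binary_mask`.
#' @export
filter_small_components <- function(mask, min_mm3, connectivity = 26L) {
  if (min_mm3 <= 0 || !any(mask$values)) return(mask)
  lab <- label_components(mask, connectivity)
  nc <- attr(lab, "ncomp")
  if (nc == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0], nbins = nc)
  vox_mm3 <- voxel_volume_um3(mask) * 1e-9
  keep <- which(sizes * vox_mm3 >= min_mm3)
  out <- array(lab %in% keep & lab > 0, dim(mask$values))
  binary_mask(out, mask$spacing, mask$channel, mask$origin)
}

#' Keep only the largest connected component
#' @inheritParams filter_small_components
#' @return A `binary_mask`.
#' @export
largest_component <- function(mask, connectivity = 26L) {
  if (!any(mask$values)) return(mask)
  lab <- label_components(mask, connectivity)
  nc <- attr(lab, "ncomp")
  sizes <- tabulate(lab[lab > 0], nbins = nc)
  out <- array(lab == which.max(sizes), dim(mask$values))
  binary_mask(out, mask$spacing, mask$channel, mask$origin)
}
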