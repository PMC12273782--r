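#' Per-brain background threshold from the contralateral hemisphere
#'
#' The linear-interpolation quantile (type 7) of the intensities under the
#' reference mask, by default the 99.9th percentile. Downstream comparisons
#' are strictly greater, so a constant background yields zero signal.
#'
#' @param grid Intensity [voxel_grid()].
#' @param reference Nonempty `binary_mask` of contralateral (uninjured)
#'   tissue on the same grid.
#' @param percentile Background percentile in (0, 100), default 99.9.
#' @return Scalar intensity threshold.
#' @export
background_threshold <- function(grid, reference, percentile = 99.9) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(reference, "binary_mask"),
            percentile > 0, percentile < 100)
  stop_if_frame_mismatch(grid, reference)
  if (!any(reference$values)) stop("empty reference mask")
  unname(stats::quantile(grid$values[reference$values], percentile / 100,
                         type = 7))
}

#' Segment supra-background signal
#'
#' Voxels strictly above the threshold, restricted to tissue, with small
#' components removed (the denoising stand-in).
#'
#' @param grid Intensity [voxel_grid()].
#' @param threshold Intensity from [background_threshold()].
#' @param tissue Tissue `binary_mask`.
#' @param min_component_mm3 Minimum retained component volume (default 1e-4).
#' @return A `binary_mask` of signal voxels.
#' @export
segment_signal <- function(grid, threshold, tissue, min_component_mm3 = 1e-4) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(tissue, "binary_mask"))
  stop_if_frame_mismatch(grid, tissue)
  m <- binary_mask(grid$values > threshold & tissue$values, grid$spacing,
                   paste0(grid$channel, ".signal"), grid$origin)
  filter_small_components(m, min_component_mm3)
}

#' Supra-threshold signal volume fraction per depth layer
#'
#' Per layer, the physical volume of signal voxels inside the layer divided
#' by the layer's tissue volume (mm^3/mm^3). Zero-tissue layers report `NA`
#' with a warning.
#'
#' @param signal Signal `binary_mask` from [segment_signal()].
#' @param layers A `depth_layer_set` on the same frame.
#' @return data.frame with `d_min_um`, `d_max_um`, `signal_volume_mm3`,
#'   `tissue_volume_mm3`, `signal_fraction`.
#' @export
signal_fraction_per_layer <- function(signal, layers) {
  stopifnot(inherits(signal, "binary_mask"),
            inherits(layers, "depth_layer_set"))
  vox_mm3 <- voxel_volume_um3(signal) * 1e-9
  sv <- vapply(layers$layers, function(l)
    sum(signal$values & l$values) * vox_mm3, numeric(1))
  tv <- layers$tissue_volumes_mm3
  frac <- ifelse(tv > 0, sv / tv, ifelse(sv > 0, NA_real_, 0))
  if (anyNA(frac))
    warning("layer with signal but zero tissue volume: fraction is NA")
  data.frame(d_min_um = layers$d_min, d_max_um = layers$d_max,
             signal_volume_mm3 = sv, tissue_volume_mm3 = tv,
             signal_fraction = frac)
}

#' Contralateral tissue reference mask
#'
#' Tissue voxels on the opposite side of the midsagittal plane from the
#' injury, the per-brain background reference. By default only the distal
#' half of the contralateral tissue (the half farthest from the midplane
#' along the left-right axis) is kept, so perilesional signal spilling
#' across the midline does not inflate the background percentile.
#'
#' @param tissue Tissue `binary_mask`.
#' @param plane A `midsagittal_plane`.
#' @param ipsilateral_side `+1` or `-1` (the injured side).
#' @param distal_fraction Fraction of the contralateral tissue extent kept,
#'   measured from the far side; 1 keeps the whole hemisphere.
#' @return A `binary_mask`.
#' @export
contralateral_mask <- function(tissue, plane, ipsilateral_side = 1L,
                               distal_fraction = 0.5) {
  stopifnot(inherits(tissue, "binary_mask"),
            inherits(plane, "midsagittal_plane"),
            distal_fraction > 0, distal_fraction <= 1)
  d <- dim(tissue$values)
  a <- plane$axis
  contra <- if (ipsilateral_side > 0) {
    seq_len(d[a]) < plane$plane_position
  } else {
    seq_len(d[a]) > plane$plane_position
  }
  side <- array(FALSE, d)
  idx <- rep(list(quote(expr = )), 3)
  idx[[a]] <- which(contra)
  side <- do.call(`[<-`, c(list(side), idx, list(TRUE)))
  m <- tissue$values & side
  if (distal_fraction < 1 && any(m)) {
    pos <- which(m, arr.ind = TRUE)[, a]
    cut <- stats::quantile(pos, if (ipsilateral_side > 0) distal_fraction
                           else 1 - distal_fraction, type = 7)
    keep_idx <- if (ipsilateral_side > 0) {
      seq_len(d[a]) <= cut
    } else {
      seq_len(d[a]) >= cut
    }
    keep <- array(FALSE, d)
    idx[[a]] <- which(keep_idx)
    keep <- do.call(`[<-`, c(list(keep), idx, list(TRUE)))
    m <- m & keep
  }
  binary_mask(m, tissue$spacing, "contralateral", tissue$origin)
}
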