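#' 3D scalar field with physical voxel spacing
#'
#' The universal raster carrier of the pipeline: a 3D array of intensities
#' plus per-axis voxel edge lengths in micrometers, a channel label, and a
#' physical origin. The physical coordinate of voxel index `(i, j, k)`
#' (1-based) along axis `a` is `(index - 1) * spacing[a] + origin[a]`.
#'
#' @param values 3D numeric array.
#' @param spacing Numeric length-3, voxel edge lengths in um (all > 0).
#' @param channel Label string; conventionally one of `"vessel"`,
#'   `"extravasation"`, `"hypoxia"`, but free-form labels are allowed.
#' @param origin Numeric length-3 physical offset in um.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, spacing, channel = "unknown",
                       origin = c(0, 0, 0)) {
  values <- as_vol3d(values)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, length(origin) == 3L)
  if (!all(is.finite(spacing)) || any(spacing <= 0))
    stop("all three spacing entries must be finite and > 0")
  structure(
    list(values = values, spacing = spacing, channel = as.character(channel),
         origin = as.numeric(origin)),
    class = "voxel_grid"
  )
}

#' Binary mask sharing a grid's geometry
#'
#' @param values 3D logical array.
#' @inheritParams voxel_grid
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing, channel = "mask",
                        origin = c(0, 0, 0)) {
  values <- as_vol3d(values)
  storage.mode(values) <- "logical"
  g <- voxel_grid(values + 0, spacing, channel, origin)
  g$values <- values
  class(g) <- c("binary_mask", "voxel_grid")
  g
}

as_vol3d <- function(values) {
  if (is.null(dim(values))) stop("values must be a 3D array, got a vector")
  if (length(dim(values)) != 3L)
    stop("values must have exactly 3 axes, got ", length(dim(values)))
  if (any(dim(values) < 1L)) stop("each axis needs at least 1 voxel")
  values
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<%s> channel '%s': %s voxels, spacing %s um\n",
              class(x)[1], x$channel,
              paste(dim(x$values), collapse = " x "),
              paste(format(x$spacing, digits = 4), collapse = " x ")))
  invisible(x)
}

#' Voxel volume of a grid in cubic micrometers
#' @param grid A `voxel_grid` or `binary_mask`.
#' @return Scalar um^3.
#' @export
voxel_volume_um3 <- function(grid) prod(grid$spacing)

same_frame <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stop_if_frame_mismatch <- function(a, b) {
  if (!same_frame(a, b))
    stop("grids must share shape, spacing and origin")
  invisible(NULL)
}

#' Physical volume of a binary mask in mm^3
#'
#' Sums the true voxels and converts via the voxel volume:
#' `count * prod(spacing um) * 1e-9` mm^3.
#'
#' @param mask A `binary_mask`.
#' @return Scalar volume in mm^3.
#' @export
mask_volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$values) * voxel_volume_um3(mask) * 1e-9
}

#' Block-mean downsampling
#'
#' Pools `factor^3` blocks by their mean; trailing partial blocks are
#' averaged over the voxels present rather than dropped, so tissue at the
#' volume border is not discarded. Output spacing is input spacing times
#' `factor`.
#'
#' @param grid A `voxel_grid`.
#' @param factor Positive integer downsampling factor.
#' @return A `voxel_grid` at the reduced resolution.
#' @export
downsample_grid <- function(grid, factor) {
  stopifnot(inherits(grid, "voxel_grid"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be an integer >= 1")
  if (factor == 1L) return(grid)
  v <- block_mean_cpp(as.numeric(grid$values), dim(grid$values), factor)
  voxel_grid(v, grid$spacing * factor, grid$channel, grid$origin)
}
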