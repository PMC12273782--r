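#' Load a 3D volume from disk
#'
#' Reads NRRD (`.nrrd`, raw-encoded, with spacing metadata) or multi-page
#' TIFF stacks (`.tif`/`.tiff`, which carry no physical spacing and need
#' `spacing_override`). Spacing from file metadata wins when present.
#'
#' @param path File path.
#' @param spacing_override Optional per-axis spacing in um, used when the file
#'   carries no spacing metadata.
#' @param channel Channel label attached to the returned grid.
#' @return A [voxel_grid()].
#' @export
load_grid <- function(path, spacing_override = NULL, channel = "unknown") {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") {
    g <- read_nrrd(path)
    if (is.null(g$spacing)) {
      if (is.null(spacing_override))
        stop("file carries no spacing metadata and no spacing_override given")
      g$spacing <- spacing_override
    }
    voxel_grid(g$values, g$spacing, channel, g$origin %||% c(0, 0, 0))
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(dim(pages[[1]])) != 2L)
      stop("expected single-sample (grayscale) TIFF pages")
    v <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
    if (is.null(spacing_override))
      stop("TIFF carries no spacing metadata; supply spacing_override")
    voxel_grid(v, spacing_override, channel)
  } else if (ext %in% c("h5", "hdf5")) {
    stop("HDF5 input is not supported; convert to NRRD or TIFF")
  } else {
    stop("unrecognized raster format '.", ext, "'")
  }
}

#' Write a volume or mask to disk
#'
#' NRRD (`.nrrd`) stores spacing and arbitrary dtypes; TIFF (`.tif`) stores
#' 16-bit integer pages and no spacing. Masks are written as uint8.
#'
#' @param grid A `voxel_grid` or `binary_mask`.
#' @param path Destination path; format chosen by extension.
#' @param type NRRD element type: one of `"double"`, `"float"`, `"uint8"`,
#'   `"int16"`, `"uint16"`, `"int32"`. Defaults to `"uint8"` for masks and
#'   `"double"` otherwise.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path, type = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(type)) type <- if (inherits(grid, "binary_mask")) "uint8" else "double"
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") {
    write_nrrd(grid, path, type)
  } else if (ext %in% c("tif", "tiff")) {
    v <- grid$values
    if (is.logical(v)) v <- v * 1L
    if (any(v < 0 | v > 65535))
      stop("TIFF output supports integer intensities in 0..65535")
    pages <- lapply(seq_len(dim(v)[3]),
                    function(k) v[, , k] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    stop("unsupported output format '.", ext, "'")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nrrd_types <- list(
  uint8  = list(what = "integer", size = 1L, signed = FALSE),
  int16  = list(what = "integer", size = 2L, signed = TRUE),
  uint16 = list(what = "integer", size = 2L, signed = FALSE),
  int32  = list(what = "integer", size = 4L, signed = TRUE),
  float  = list(what = "numeric", size = 4L, signed = TRUE),
  double = list(what = "numeric", size = 8L, signed = TRUE)
)

# Minimal NRRD0004 reader: raw encoding, attached data, little endian,
# 3-dimensional, spacing via `spacings` or diagonal `space directions`.
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    fields[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
  }
  type <- fields[["type"]]
  type <- switch(type,
    "unsigned char" = "uint8", "uchar" = "uint8",
    "short" = "int16", "unsigned short" = "uint16", "ushort" = "uint16",
    "int" = "int32", type)
  spec <- nrrd_types[[type]]
  if (is.null(spec)) stop("unsupported NRRD type: ", type)
  if (!is.null(fields[["encoding"]]) && fields[["encoding"]] != "raw")
    stop("only raw NRRD encoding is supported")
  ndim <- as.integer(fields[["dimension"]])
  if (!identical(ndim, 3L)) stop("expected 3-dimensional NRRD, got ", ndim, "D")
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  spacing <- NULL
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3))
    spacing <- sqrt(colSums(m^2))
  }
  origin <- NULL
  if (!is.null(fields[["axis mins"]]))
    origin <- as.numeric(strsplit(fields[["axis mins"]], "\\s+")[[1]])
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])
  n <- prod(sizes)
  v <- readBin(con, what = spec$what, n = n, size = spec$size,
               signed = spec$signed, endian = "little")
  if (length(v) != n) stop("truncated NRRD data block")
  dim(v) <- sizes
  list(values = v, spacing = spacing, origin = origin)
}

write_nrrd <- function(grid, path, type = "double") {
  spec <- nrrd_types[[type]]
  if (is.null(spec)) stop("unsupported NRRD type: ", type)
  v <- grid$values
  if (is.logical(v)) v <- v * 1L
  if (spec$what == "integer" && !is.integer(v)) {
    vi <- as.integer(round(v))
    if (max(abs(v - vi)) > 0)
      warning("non-integer intensities rounded for integer NRRD type")
    v <- vi
  }
  con <- file(path, "wb")
  on.exit(close(con))
  header <- c(
    "NRRD0004",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(dim(grid$values), collapse = " ")),
    paste0("spacings: ", paste(format(grid$spacing, digits = 17), collapse = " ")),
    paste0("axis mins: ", paste(format(grid$origin, digits = 17), collapse = " ")),
    "endian: little",
    "encoding: raw",
    ""
  )
  writeLines(header, con, sep = "\n")
  if (spec$what == "integer" && spec$size %in% c(1L, 2L) &&
      any(v > .Machine$integer.max / 2)) {
    # writeBin handles sizes 1/2 by truncation; range-check first
  }
  writeBin(if (spec$what == "numeric") as.numeric(v) else as.integer(v), con,
           size = spec$size, endian = "little")
  invisible(path)
}
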