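#' Image volumes
#'
#' An `image_volume` is the package's container for a 2D image or a 3D image
#' stack: a numeric array of non-negative intensities indexed `(x, y, z)`,
#' with `nz = 1` for 2D images.  Coordinates used throughout the package are
#' 0-based voxel indices, so voxel `(x, y, z)` is `voxels(v)[x + 1, y + 1, z + 1]`.
#'
#' @param voxels numeric matrix (2D) or 3D array of finite, non-negative
#'   intensities, indexed `(x, y, z)`.
#' @param source_path optional path the volume was read from.
#' @param channel channel provenance: `"all"` (collapsed), `"red"`, `"green"`,
#'   `"blue"` or a positive channel index.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, source_path = NA_character_, channel = "all") {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  if (!is.array(voxels) || length(dim(voxels)) != 3L || !is.numeric(voxels)) {
    stop("'voxels' must be a numeric matrix or 3D array")
  }
  if (anyNA(voxels) || any(!is.finite(voxels))) {
    stop("image intensities must all be finite")
  }
  if (any(voxels < 0)) stop("image intensities must be non-negative")
  storage.mode(voxels) <- "double"
  structure(
    list(voxels = voxels, source_path = source_path, channel = channel),
    class = "image_volume"
  )
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

#' Voxel array of an image volume
#' @param v an `image_volume`.
#' @return The underlying 3D numeric array, indexed `(x, y, z)`.
#' @export
voxels <- function(v) v$voxels

is_2d <- function(v) dim(v)[3] == 1L

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<image_volume> %d x %d x %d, channel=%s, range [%g, %g]\n",
    d[1], d[2], d[3], as.character(x$channel),
    min(x$voxels), max(x$voxels)
  ))
  invisible(x)
}

# Select one channel from an (y, x[, ch]) plane as returned by png/tiff
# readers, returning an (x, y) matrix.  channel "all" collapses multi-channel
# data by the mean across channels.
channel_select <- function(page, channel) {
  if (length(dim(page)) == 2L || is.null(dim(page))) {
    page <- as.matrix(page)
    idx <- channel_index(channel, 1L)
    return(t(page))
  }
  nch <- dim(page)[3]
  idx <- channel_index(channel, nch)
  plane <- if (is.na(idx)) {
    apply(page, c(1, 2), mean)
  } else {
    page[, , idx]
  }
  t(plane)
}

# Map a channel selector to an index; NA means collapse-all.
channel_index <- function(channel, nch) {
  if (identical(channel, "all")) return(NA_integer_)
  idx <- switch(as.character(channel),
    red = 1L, green = 2L, blue = 3L,
    {
      if (!is_count(channel)) stop("invalid channel selector: ", channel)
      as.integer(channel)
    }
  )
  if (idx > nch) {
    stop(sprintf("channel index %d out of range: image has %d channel(s)", idx, nch))
  }
  idx
}

png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 26L) return(8L)
  as.integer(hdr[25L])
}

#' Read a 2D image or 3D stack
#'
#' Reads a PNG, a single-page TIFF (2D, `nz = 1`) or a multi-page TIFF (one
#' slice per page).  For multi-channel images only the selected channel is
#' kept; `channel = "all"` averages the channels.  Integer sample values are
#' preserved exactly (not rescaled to `[0, 1]`).
#'
#' @param path path to a PNG or (multi-page) TIFF file.
#' @param channel `"all"`, `"red"`, `"green"`, `"blue"` or a channel index.
#' @return An [image_volume()].
#' @export
read_image_volume <- function(path, channel = "all") {
  if (!file.exists(path)) stop_data("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pages <- switch(ext,
    png = {
      img <- tryCatch(png::readPNG(path), error = function(e) {
        stop_data("cannot read PNG '", path, "': ", conditionMessage(e))
      })
      maxval <- 2^png_bit_depth(path) - 1
      list(round(img * maxval))
    },
    tif = ,
    tiff = {
      img <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
        error = function(e) {
          stop_data("cannot read TIFF '", path, "': ", conditionMessage(e))
        }
      )
      if (!is.list(img)) img <- list(img)
      img
    },
    stop_data("unsupported image format '", ext, "' for: ", path)
  )
  slices <- lapply(pages, channel_select, channel = channel)
  vox <- array(0, dim = c(dim(slices[[1]]), length(slices)))
  for (k in seq_along(slices)) vox[, , k] <- slices[[k]]
  image_volume(vox, source_path = path, channel = channel)
}

#' Write an image volume as a 16-bit (multi-page) TIFF
#'
#' Intensities are rounded to integers and must fit in 16 bits; the values
#' read back by [read_image_volume()] equal `round(voxels(v))` exactly.
#'
#' @param v an `image_volume`.
#' @param path output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_image_volume <- function(v, path) {
  vox <- round(voxels(v))
  if (max(vox) > 65535) stop("intensities exceed 16-bit range")
  pages <- lapply(seq_len(dim(v)[3]), function(k) t(vox[, , k]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Crop an image volume
#'
#' Ranges are 0-based, inclusive voxel indices.
#'
#' @param v an `image_volume`.
#' @param x,y,z length-2 integer vectors `c(lo, hi)`, 0-based inclusive;
#'   `NULL` keeps the full axis.
#' @return The cropped `image_volume`.
#' @export
crop_volume <- function(v, x = NULL, y = NULL, z = NULL) {
  d <- dim(v)
  rng <- function(r, n) {
    if (is.null(r)) return(seq_len(n))
    if (r[1] < 0 || r[2] >= n || r[1] > r[2]) stop("crop range out of bounds")
    (r[1] + 1L):(r[2] + 1L)
  }
  image_volume(
    v$voxels[rng(x, d[1]), rng(y, d[2]), rng(z, d[3]), drop = FALSE],
    source_path = v$source_path, channel = v$channel
  )
}

#' Coordinate lists
#'
#' Coordinates are 0-based voxel indices stored as a data frame with columns
#' `x`, `y`, `z` (`z = 0` for 2D images).
#'
#' @param x,y,z integer vectors of equal length (or scalars, recycled).
#' @return A `data.frame` with columns `x`, `y`, `z`.
#' @export
coordinates <- function(x = integer(), y = integer(), z = 0L) {
  data.frame(x = as.integer(x), y = as.integer(y), z = as.integer(rep_len(z, length(x))))
}

coords_in_bounds <- function(coords, dims) {
  coords$x >= 0 & coords$x < dims[1] &
    coords$y >= 0 & coords$y < dims[2] &
    coords$z >= 0 & coords$z < dims[3]
}
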