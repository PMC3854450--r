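#' Patch geometry
#'
#' A patch is the fixed-size neighborhood of a voxel used as one
#' classification sample in ROI mode: it spans
#' `(2*rx+1) x (2*ry+1) x (2*rz+1)` voxels around its center.  `rz = 0`
#' degenerates to a 2D patch.
#'
#' @param rx,ry,rz non-negative integer half-widths.
#' @return An object of class `patch_geometry`.
#' @export
patch_geometry <- function(rx, ry, rz = 0L) {
  if (!is_count(rx, 0L) || !is_count(ry, 0L) || !is_count(rz, 0L)) {
    stop("rx, ry, rz must be non-negative integers")
  }
  structure(list(rx = as.integer(rx), ry = as.integer(ry), rz = as.integer(rz)),
            class = "patch_geometry")
}

#' @export
print.patch_geometry <- function(x, ...) {
  cat(sprintf("<patch_geometry> %dx%dx%d (rx=%d, ry=%d, rz=%d)\n",
              2 * x$rx + 1, 2 * x$ry + 1, 2 * x$rz + 1, x$rx, x$ry, x$rz))
  invisible(x)
}

#' Extract the patch around a voxel
#'
#' Returns the `(2*rx+1) x (2*ry+1) x (2*rz+1)` sub-volume centered on
#' `center`; voxels falling outside the image are zero-filled, matching the
#' dark background of fluorescence imagery.  The center itself must lie
#' inside the volume.
#'
#' @param v an [image_volume()].
#' @param center a single-row [coordinates()] data frame or numeric `c(x, y, z)`
#'   (0-based).
#' @param geometry a [patch_geometry()].
#' @return An `image_volume` holding the patch.
#' @export
extract_patch <- function(v, center, geometry) {
  if (is.data.frame(center)) center <- c(center$x[1], center$y[1], center$z[1])
  center <- as.integer(center)
  d <- dim(v)
  if (any(center < 0L) || any(center >= d)) {
    stop("patch center (", paste(center, collapse = ","), ") outside volume")
  }
  r <- c(geometry$rx, geometry$ry, geometry$rz)
  side <- 2L * r + 1L
  patch <- array(0, dim = side)
  src_lo <- pmax(center - r, 0L)
  src_hi <- pmin(center + r, d - 1L)
  dst_lo <- src_lo - (center - r)
  patch[
    (dst_lo[1] + 1L):(dst_lo[1] + src_hi[1] - src_lo[1] + 1L),
    (dst_lo[2] + 1L):(dst_lo[2] + src_hi[2] - src_lo[2] + 1L),
    (dst_lo[3] + 1L):(dst_lo[3] + src_hi[3] - src_lo[3] + 1L)
  ] <- v$voxels[
    (src_lo[1] + 1L):(src_hi[1] + 1L),
    (src_lo[2] + 1L):(src_hi[2] + 1L),
    (src_lo[3] + 1L):(src_hi[3] + 1L)
  ]
  image_volume(patch, source_path = v$source_path, channel = v$channel)
}
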