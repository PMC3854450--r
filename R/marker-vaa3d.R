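# Vaa3D landmark (.marker) files: comma-separated text, one landmark per
# line, "x,y,z,radius,shape,name,comment", with '#' comment lines.  Vaa3D
# stores 1-based voxel coordinates; the package's internal convention is
# 0-based, so markers are shifted by -1 on read and +1 on write.

#' Read a Vaa3D marker (landmark) file
#'
#' @param path path to a `.marker` text file.
#' @return A [coordinates()] data frame of 0-based voxel coordinates.
#' @export
read_vaa3d_marker <- function(path) {
  if (!file.exists(path)) stop_data("marker file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) return(coordinates())
  xs <- ys <- zs <- integer(length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    fields <- strsplit(lines[ln], ",", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop_data(sprintf("line %d of '%s': expected at least x,y,z fields", ln, path))
    }
    xyz <- suppressWarnings(as.numeric(fields[1:3]))
    if (anyNA(xyz)) {
      stop_data(sprintf("line %d of '%s': non-numeric coordinate field", ln, path))
    }
    xs[i] <- xyz[1]; ys[i] <- xyz[2]; zs[i] <- xyz[3]
  }
  coordinates(xs - 1L, ys - 1L, zs - 1L)
}

#' Write coordinates as a Vaa3D marker file
#'
#' Inverse of [read_vaa3d_marker()]: internal 0-based coordinates are written
#' 1-based, as Vaa3D expects.
#'
#' @param coords a [coordinates()] data frame.
#' @param path output path.
#' @param name optional per-marker names (recycled).
#' @return `path`, invisibly.
#' @export
write_vaa3d_marker <- function(coords, path, name = "") {
  name <- rep_len(name, max(nrow(coords), 1L))
  lines <- c(
    "#x,y,z,radius,shape,name,comment",
    sprintf("%d,%d,%d,0,1,%s,", coords$x + 1L, coords$y + 1L, coords$z + 1L,
            name[seq_len(nrow(coords))])
  )
  writeLines(lines, path)
  invisible(path)
}
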