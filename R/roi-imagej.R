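# ImageJ ROI archives.
#
# An ImageJ ROI zip is an ordinary ZIP archive whose members are binary .roi
# records (magic "Iout", big-endian, 64-byte header).  Point ROIs carry their
# coordinates as int16 offsets relative to the bounding box; rectangle/oval
# ROIs are reduced to their integer centers.  ImageJ coordinates are treated
# as already 0-based (see read_vaa3d_marker for the 1-based convention).

ROI_TYPE_RECT <- 1L
ROI_TYPE_OVAL <- 2L
ROI_TYPE_POINT <- 10L

# ---- .roi record encoding ---------------------------------------------------

encode_point_roi <- function(xs, ys) {
  n <- length(xs)
  left <- min(xs); top <- min(ys)
  header <- raw(64)
  header[1:4] <- charToRaw("Iout")
  wr_short <- function(h, off, val) {
    # big-endian int16 at 0-based byte offset `off`
    v <- as.integer(val) %% 65536L
    h[off + 1L] <- as.raw(v %/% 256L)
    h[off + 2L] <- as.raw(v %% 256L)
    h
  }
  header <- wr_short(header, 4L, 227L)             # version
  header[7L] <- as.raw(ROI_TYPE_POINT)             # roi type
  header <- wr_short(header, 8L, top)
  header <- wr_short(header, 10L, left)
  header <- wr_short(header, 12L, max(ys) + 1L)    # bottom (exclusive)
  header <- wr_short(header, 14L, max(xs) + 1L)    # right  (exclusive)
  header <- wr_short(header, 16L, n)               # nCoordinates
  body <- raw(4L * n)
  rel <- c(xs - left, ys - top)
  for (i in seq_along(rel)) {
    v <- as.integer(rel[i]) %% 65536L
    body[2L * i - 1L] <- as.raw(v %/% 256L)
    body[2L * i] <- as.raw(v %% 256L)
  }
  c(header, body)
}

rd_short <- function(bytes, off, signed = TRUE) {
  v <- as.integer(bytes[off + 1L]) * 256L + as.integer(bytes[off + 2L])
  if (signed && v >= 32768L) v <- v - 65536L
  v
}

decode_roi <- function(bytes, member = "<roi>") {
  if (length(bytes) < 64L || rawToChar(bytes[1:4]) != "Iout") {
    stop_data("not an ImageJ ROI record: ", member)
  }
  type <- as.integer(bytes[7L])
  top <- rd_short(bytes, 8L); left <- rd_short(bytes, 10L)
  bottom <- rd_short(bytes, 12L); right <- rd_short(bytes, 14L)
  n <- rd_short(bytes, 16L, signed = FALSE)
  if (type == ROI_TYPE_POINT || type == 0L) {
    if (length(bytes) < 64L + 4L * n) stop_data("truncated ROI record: ", member)
    xs <- ys <- integer(n)
    for (i in seq_len(n)) {
      xs[i] <- left + rd_short(bytes, 64L + 2L * (i - 1L))
      ys[i] <- top + rd_short(bytes, 64L + 2L * n + 2L * (i - 1L))
    }
    coordinates(xs, ys)
  } else if (type %in% c(ROI_TYPE_RECT, ROI_TYPE_OVAL)) {
    # integer center of the bounding box (right/bottom are exclusive)
    coordinates(left + (right - left) %/% 2L, top + (bottom - top) %/% 2L)
  } else {
    stop_data(sprintf("unsupported ROI type %d in member: %s", type, member))
  }
}

#' Read point coordinates from an ImageJ ROI zip archive
#'
#' Point ROIs yield their coordinates; rectangle and oval ROIs are reduced to
#' their integer centers.  Coordinates are returned in the package's 0-based
#' convention with `z = 0`.
#'
#' @param path path to a `.zip` archive of ImageJ `.roi` records.
#' @return A [coordinates()] data frame.
#' @export
read_imagej_roi_zip <- function(path) {
  if (!file.exists(path)) stop_data("ROI archive not found: ", path)
  members <- tryCatch(utils::unzip(path, list = TRUE),
    error = function(e) stop_data("not a readable zip archive: ", path),
    warning = function(w) stop_data("not a readable zip archive: ", path)
  )
  if (nrow(members) == 0L) return(coordinates())
  exdir <- tempfile("roizip")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  utils::unzip(path, exdir = exdir)
  out <- lapply(sort(members$Name), function(m) {
    f <- file.path(exdir, m)
    decode_roi(readBin(f, "raw", n = file.size(f)), member = m)
  })
  do.call(rbind, out)
}

#' Write point coordinates as an ImageJ ROI zip archive
#'
#' Each coordinate becomes one single-point `.roi` member, so the archive can
#' be loaded by ImageJ's ROI manager.  `read_imagej_roi_zip()` inverts this
#' exactly.
#'
#' @param coords a [coordinates()] data frame (`z` is ignored; ImageJ point
#'   ROIs are planar).
#' @param path output `.zip` path.
#' @return `path`, invisibly.
#' @export
write_imagej_roi_zip <- function(coords, path) {
  entries <- lapply(seq_len(nrow(coords)), function(i) {
    list(
      name = sprintf("%04d-point.roi", i),
      data = encode_point_roi(coords$x[i], coords$y[i])
    )
  })
  write_stored_zip(entries, path)
  invisible(path)
}

# ---- minimal ZIP writer (stored entries, no compression) --------------------

crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (i in 1:8) {
      c <- if (bitwAnd(c, 1L) == 1L) {
        bitwXor(bitwShiftR(c, 1L), -306674912L) # 0xEDB88320
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[n + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L
  for (b in as.integer(bytes)) {
    c <- bitwXor(bitwShiftR(c, 8L), crc32_table[bitwAnd(bitwXor(c, b), 255L) + 1L])
  }
  bitwXor(c, -1L)
}

le_bytes <- function(value, n) {
  # little-endian unsigned integer as n raw bytes (value may be a signed
  # 32-bit int holding an unsigned bit pattern, e.g. a CRC)
  v <- as.double(value)
  if (v < 0) v <- v + 4294967296
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(v %% 256)
    v <- v %/% 256
  }
  out
}

write_stored_zip <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  offsets <- integer(length(entries))
  pos <- 0L
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    name <- charToRaw(e$name)
    crc <- crc32(e$data)
    local_hdr <- c(
      as.raw(c(0x50, 0x4b, 0x03, 0x04)), le_bytes(20, 2), le_bytes(0, 2),
      le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 2),
      le_bytes(crc, 4), le_bytes(length(e$data), 4), le_bytes(length(e$data), 4),
      le_bytes(length(name), 2), le_bytes(0, 2), name
    )
    offsets[i] <- pos
    writeBin(local_hdr, con)
    writeBin(e$data, con)
    pos <- pos + length(local_hdr) + length(e$data)
  }
  central <- raw(0)
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    name <- charToRaw(e$name)
    central <- c(central,
      as.raw(c(0x50, 0x4b, 0x01, 0x02)), le_bytes(20, 2), le_bytes(20, 2),
      le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 2),
      le_bytes(crc32(e$data), 4), le_bytes(length(e$data), 4),
      le_bytes(length(e$data), 4), le_bytes(length(name), 2),
      le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 2),
      le_bytes(0, 4), le_bytes(offsets[i], 4), name
    )
  }
  writeBin(central, con)
  eocd <- c(
    as.raw(c(0x50, 0x4b, 0x05, 0x06)), le_bytes(0, 2), le_bytes(0, 2),
    le_bytes(length(entries), 2), le_bytes(length(entries), 2),
    le_bytes(length(central), 4), le_bytes(pos, 4), le_bytes(0, 2)
  )
  writeBin(eocd, con)
  invisible(path)
}
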