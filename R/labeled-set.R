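# Label association: the three ways a training label reaches an image.
#
#  a) target-file mode:    a text file mapping image name -> one or more labels
#  b) directory-tree mode: one subdirectory per class
#  c) roi mode:            ImageJ ROI zip / Vaa3D marker files whose base name
#                          is the class, over a single image
#
# Whole-image modes yield a `labeled_image_set`; roi mode yields a `roi_set`
# of labeled voxel coordinates plus the shared patch geometry.

IMAGE_EXTS <- c("png", "tif", "tiff")

new_labeled_image_set <- function(entries, classes, mode) {
  structure(list(entries = entries, classes = classes, mode = mode),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cat(sprintf("<labeled_image_set> %d entries, %d classes (%s), mode=%s\n",
              length(x$entries), length(x$classes),
              paste(x$classes, collapse = ", "), x$mode))
  invisible(x)
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d labeled points over '%s', classes: %s\n",
              nrow(x$points), x$image, paste(x$classes, collapse = ", ")))
  print(x$geometry)
  invisible(x)
}

#' Load a labeled image set from a directory tree
#'
#' Each immediate subdirectory of `root` is a class; every PNG/TIFF file in it
#' is one single-label entry.  Entries are ordered by (class name, file name),
#' so loading is deterministic.  Empty class directories are dropped with a
#' warning.
#'
#' @param root directory with one subdirectory per class.
#' @return A `labeled_image_set`.
#' @export
load_directory_tree <- function(root) {
  if (!dir.exists(root)) stop_data("directory not found: ", root)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  entries <- list()
  kept <- character()
  for (cls in classes) {
    files <- sort(list.files(file.path(root, cls),
      pattern = sprintf("\\.(%s)$", paste(IMAGE_EXTS, collapse = "|")),
      ignore.case = TRUE
    ))
    if (length(files) == 0L) {
      warning("class directory '", cls, "' contains no images; class dropped")
      next
    }
    kept <- c(kept, cls)
    entries <- c(entries, lapply(files, function(f) {
      list(image = file.path(root, cls, f), labels = cls)
    }))
  }
  new_labeled_image_set(entries, kept, "directory-tree")
}

#' Load a labeled image set from a target file
#'
#' Each non-empty line is `image-name label [label ...]` (whitespace
#' separated); an image may carry several labels.  Image names are resolved
#' relative to the target file's directory.
#'
#' @param path path to the target file.
#' @return A `labeled_image_set` (mode `"target-file"`).
#' @export
load_target_file <- function(path) {
  if (!file.exists(path)) stop_data("target file not found: ", path)
  base <- dirname(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  entries <- list()
  missing <- character()
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 2L) {
      stop_data("target file line without a label: '", ln, "'")
    }
    img <- file.path(base, tok[1])
    if (!file.exists(img)) missing <- c(missing, tok[1])
    entries[[length(entries) + 1L]] <- list(image = img, labels = unique(tok[-1]))
  }
  if (length(missing) > 0L) {
    stop_data("target file references missing image(s): ",
              paste(unique(missing), collapse = ", "))
  }
  classes <- sort(unique(unlist(lapply(entries, `[[`, "labels"))))
  new_labeled_image_set(entries, classes, "target-file")
}

#' Load a labeled ROI set from ROI/landmark files
#'
#' Each ROI file (ImageJ `.zip` of ROI records, or Vaa3D `.marker` text)
#' contributes its points under the class named by the file's base name
#' (`pos.zip` -> class `"pos"`).  All points must lie inside the image.
#'
#' @param image path to the image the ROIs refer to.
#' @param roi_files character vector of ROI/marker file paths.
#' @param geometry the shared [patch_geometry()] defining the training
#'   volumes around each point.
#' @return A `roi_set`: labeled points plus the patch geometry.
#' @export
load_roi_set <- function(image, roi_files, geometry) {
  if (!inherits(geometry, "patch_geometry")) stop("'geometry' must be a patch_geometry")
  vol_dim <- dim(read_image_volume(image))
  pts <- list()
  for (f in sort(roi_files)) {
    cls <- tools::file_path_sans_ext(basename(f))
    co <- switch(tolower(tools::file_ext(f)),
      zip = read_imagej_roi_zip(f),
      marker = ,
      txt = read_vaa3d_marker(f),
      stop_data("unsupported ROI file format: ", f)
    )
    if (nrow(co) == 0L) next
    if (!all(coords_in_bounds(co, vol_dim))) {
      stop_data("ROI file '", f, "' contains points outside the image bounds")
    }
    co$label <- cls
    pts[[length(pts) + 1L]] <- co
  }
  points <- if (length(pts)) do.call(rbind, pts) else
    cbind(coordinates(), label = character())
  structure(
    list(image = image, points = points,
         classes = sort(unique(points$label)), geometry = geometry),
    class = "roi_set"
  )
}

#' Load training labels in any of the three association modes
#'
#' Dispatcher over [load_directory_tree()], [load_target_file()] and
#' [load_roi_set()], driven by a label-source specification as used in chain
#' configuration files.
#'
#' @param source a list with `mode` (one of `"directory-tree"`,
#'   `"target-file"`, `"roi"`) plus `path` (tree root or target file), or for
#'   roi mode: `image`, `roi_files` and `geometry`.
#' @return A `labeled_image_set` or `roi_set`.
#' @export
load_labeled_set <- function(source) {
  mode <- source$mode %||% stop_config("label source must name a 'mode'")
  switch(mode,
    "directory-tree" = load_directory_tree(source$path),
    "target-file" = load_target_file(source$path),
    "roi" = load_roi_set(source$image, source$roi_files, source$geometry),
    stop_config("unknown label-source mode '", mode,
                "' (expected directory-tree, target-file or roi)")
  )
}
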