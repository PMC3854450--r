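# Applying a trained model to new images: sliding-window voxel/pixel
# annotation, local-maxima restriction, mean-shift center merging for object
# counting, and multi-label whole-image annotation.

#' Local maximum voxels by grayscale dilation
#'
#' A voxel is a local maximum iff its intensity equals the grayscale dilation
#' of the image at that position under a cubic structuring element of the
#' given radius, and exceeds the intensity floor.  Within a constant plateau
#' above the floor only one representative is returned: the lexicographically
#' smallest coordinate (by `x`, then `y`, then `z`).  Restricting annotation
#' decisions to local maxima makes counting bright objects in largely dark
#' volumes efficient.
#'
#' @param v an [image_volume()].
#' @param radius structuring-element half-width, default 1.
#' @param floor intensity floor; defaults to the Otsu threshold of `v`.
#' @return A [coordinates()] data frame.
#' @export
local_maxima <- function(v, radius = 1L, floor = NULL) {
  if (!is_count(radius)) stop("'radius' must be a positive integer")
  floor <- floor %||% otsu_threshold(v)
  vox <- v$voxels
  d <- dim(vox)
  dz <- if (d[3] > 1L) seq(-radius, radius) else 0L
  nmax <- array(-Inf, d)
  for (ddx in seq(-radius, radius)) {
    for (ddy in seq(-radius, radius)) {
      for (ddz in dz) {
        if (ddx == 0L && ddy == 0L && ddz == 0L) next
        sx <- intersect(seq_len(d[1]), seq_len(d[1]) - ddx)
        sy <- intersect(seq_len(d[2]), seq_len(d[2]) - ddy)
        sz <- intersect(seq_len(d[3]), seq_len(d[3]) - ddz)
        nmax[sx, sy, sz] <- pmax(
          nmax[sx, sy, sz, drop = FALSE],
          vox[sx + ddx, sy + ddy, sz + ddz, drop = FALSE]
        )
      }
    }
  }
  cand <- vox >= nmax & vox > floor
  if (!any(cand)) return(coordinates())
  # adjacent candidates necessarily share one intensity, so connected
  # candidate components are exactly the constant plateaus
  labels <- label_components(cand)
  idx <- which(labels > 0L)
  co <- arrayInd(idx, d) - 1L
  comp <- labels[idx]
  ord <- order(comp, co[, 1], co[, 2], co[, 3])
  first <- ord[!duplicated(comp[ord])]
  out <- coordinates(co[first, 1], co[first, 2], co[first, 3])
  out[order(out$x, out$y, out$z), , drop = FALSE]
}

# feature matrix of the model's extractors over patches at given sites
featurize_sites <- function(model, v, sites) {
  fns <- lapply(model$chain$extractors, resolve_extractor)
  names(fns) <- vapply(model$chain$extractors, `[[`, "", "name")
  rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    patch <- extract_patch(v, sites[i, ], model$geometry)
    vec <- lapply(seq_along(fns), function(j) {
      out <- fns[[j]](patch)
      if (is.null(names(out))) {
        names(out) <- sprintf("%s.%d", names(fns)[j], seq_along(out))
      }
      out
    })
    rows[[i]] <- unlist(vec)
  }
  do.call(rbind, rows)
}

#' Sliding-window annotation of an image
#'
#' Applies a trained ROI model at decision sites: the lattice
#' `{0, interval, 2*interval, ...}` along each axis, or an explicit
#' coordinate list (e.g. [local_maxima()]) via `restrict_to`.  At each site
#' the patch around the voxel is extracted (zero-padded at borders, so with
#' `interval = 1` literally every voxel is annotated), the model's extractors
#' and selector mapping are applied, and the classifier assigns a label.
#'
#' @param model a `trained_model` carrying a [patch_geometry()] (ROI mode).
#' @param v an [image_volume()] at least as large as one patch.
#' @param interval voxels between decisions (default 1: every voxel).
#' @param restrict_to optional [coordinates()] of decision sites, overriding
#'   the lattice.
#' @return A data frame of class `annotation_grid` with columns
#'   `x`, `y`, `z`, `label`; attributes `interval` and `classes`.
#' @export
sliding_annotate <- function(model, v, interval = 1L, restrict_to = NULL) {
  if (is.null(model$geometry)) {
    stop_contract("model carries no patch geometry; it was not trained on ROIs")
  }
  if (!is_count(interval)) stop("'interval' must be a positive integer")
  d <- dim(v)
  g <- model$geometry
  if (any(d < c(2 * g$rx + 1, 2 * g$ry + 1, 2 * g$rz + 1))) {
    stop_contract("volume is smaller than one model patch")
  }
  sites <- if (is.null(restrict_to)) {
    zs <- if (d[3] > 1L) seq(0L, d[3] - 1L, by = interval) else 0L
    expand.grid(
      x = seq(0L, d[1] - 1L, by = interval),
      y = seq(0L, d[2] - 1L, by = interval),
      z = zs
    )
  } else {
    if (!all(coords_in_bounds(restrict_to, d))) {
      stop("restrict_to contains out-of-bounds coordinates")
    }
    restrict_to[, c("x", "y", "z")]
  }
  feats <- featurize_sites(model, v, sites)
  x <- model_select_features(model, feats)
  labels <- predict(model$classifier, x)
  out <- data.frame(x = sites$x, y = sites$y, z = sites$z,
                    label = labels, stringsAsFactors = FALSE)
  structure(out, interval = as.integer(interval), classes = model$classes,
            source = v$source_path,
            class = c("annotation_grid", class(out)))
}

#' Write annotation outputs
#'
#' Writes `decisions.csv` (x, y, z, label) and a label-indexed mask as a
#' 16-bit TIFF (`mask.tif`; value k = k-th class, 0 = no decision at that
#' voxel); colorization is left to viewers.
#'
#' @param grid an `annotation_grid` from [sliding_annotate()].
#' @param dir output directory.
#' @param dims volume dimensions `c(nx, ny, nz)` for the mask.
#' @return `dir`, invisibly.
#' @export
write_annotation <- function(grid, dir, dims) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(grid), file.path(dir, "decisions.csv"),
                   row.names = FALSE)
  mask <- array(0, dims)
  cls <- attr(grid, "classes")
  mask[cbind(grid$x + 1L, grid$y + 1L, grid$z + 1L)] <- match(grid$label, cls)
  write_image_volume(image_volume(mask), file.path(dir, "mask.tif"))
  writeLines(cls, file.path(dir, "classes.txt"))
  invisible(dir)
}

# intensity-weighted centroid of the spherical neighborhood of a point
shift_once <- function(pt, vox, d, radius) {
  lo <- pmax(floor(pt - radius), 0)
  hi <- pmin(ceiling(pt + radius), d - 1L)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  grid <- expand.grid(x = xs, y = ys, z = zs)
  dist2 <- (grid$x - pt[1])^2 + (grid$y - pt[2])^2 + (grid$z - pt[3])^2
  inside <- dist2 <= radius^2
  if (!any(inside)) return(pt)
  g <- grid[inside, ]
  w <- vox[cbind(g$x + 1L, g$y + 1L, g$z + 1L)]
  if (sum(w) <= 0) return(pt)
  c(sum(g$x * w), sum(g$y * w), sum(g$z * w)) / sum(w)
}

#' Merge detected centers by mean shift and count objects
#'
#' Each candidate is iterated by mean shift -- moved to the intensity-weighted
#' centroid of its spherical neighborhood -- until the displacement falls
#' below `tol` voxels or `max_iter` iterations.  Converged points closer than
#' `merge_radius` are agglomerated by single linkage; each cluster
#' contributes one center (the intensity-weighted mean of its members) and
#' the object count is the cluster count.
#'
#' @param candidates a [coordinates()] data frame of detected centers.
#' @param v the [image_volume()] the candidates refer to.
#' @param merge_radius merge distance in voxels.
#' @param shift_radius mean-shift window radius; defaults to `merge_radius`.
#' @param tol convergence displacement, default 0.5 voxel.
#' @param max_iter mean-shift iteration cap, default 50.
#' @return A list with `count` and `centers` (a [coordinates()] data frame of
#'   rounded cluster centers).
#' @export
merge_centers <- function(candidates, v, merge_radius = 3,
                          shift_radius = merge_radius, tol = 0.5,
                          max_iter = 50L) {
  if (nrow(candidates) == 0L) {
    return(list(count = 0L, centers = coordinates()))
  }
  d <- dim(v)
  if (!all(coords_in_bounds(candidates, d))) {
    stop("candidates contain out-of-bounds coordinates")
  }
  vox <- v$voxels
  pts <- matrix(0, nrow(candidates), 3)
  for (i in seq_len(nrow(candidates))) {
    pt <- c(candidates$x[i], candidates$y[i], candidates$z[i])
    for (it in seq_len(max_iter)) {
      nxt <- shift_once(pt, vox, d, shift_radius)
      if (sqrt(sum((nxt - pt)^2)) < tol) {
        pt <- nxt
        break
      }
      pt <- nxt
    }
    pts[i, ] <- pt
  }
  if (nrow(pts) == 1L) {
    cl <- 1L
  } else {
    cl <- stats::cutree(stats::hclust(stats::dist(pts), method = "single"),
                        h = merge_radius)
  }
  centers <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    member <- pts[cl == k, , drop = FALSE]
    w <- vox[cbind(round(member[, 1]) + 1L, round(member[, 2]) + 1L,
                   round(member[, 3]) + 1L)]
    if (sum(w) <= 0) w <- rep(1, nrow(member))
    colSums(member * w) / sum(w)
  }))
  list(
    count = length(unique(cl)),
    centers = coordinates(round(centers[, 1]), round(centers[, 2]),
                          round(centers[, 3]))
  )
}

#' Restrict a labeled image set to presence/absence of one label
#'
#' Helper for multi-label annotation: converts a (possibly multi-label) set
#' into the binary problem "is `label` present?", with classes `label` and
#' `absent`.
#'
#' @param set a `labeled_image_set`.
#' @param label the label of interest.
#' @return A single-label `labeled_image_set` with classes
#'   `c(label, "absent")`.
#' @export
binary_label_set <- function(set, label) {
  entries <- lapply(set$entries, function(e) {
    list(image = e$image,
         labels = if (label %in% e$labels) label else "absent")
  })
  new_labeled_image_set(entries, sort(c(label, "absent")), set$mode)
}

#' Multi-label image annotation
#'
#' Formulates annotation as multiple binary problems: one present/absent
#' model per label.  A label is in an image's output set iff its binary model
#' predicts the label; the consolidated report lists every image with its
#' (possibly empty) label set.
#'
#' @param models named list mapping label -> binary `trained_model` (each
#'   trained on 2 classes, one of which is the label).
#' @param images character vector of image paths or a `labeled_image_set`.
#' @return An object of class `multilabel_report`: a data frame with columns
#'   `image` and `labels` (comma-joined, possibly empty), plus a logical
#'   matrix attribute `presence`.
#' @export
multilabel_annotate <- function(models, images) {
  if (is.null(names(models)) || any(names(models) == "")) {
    stop("'models' must be a named list (label -> model)")
  }
  for (lab in names(models)) {
    m <- models[[lab]]
    if (length(m$classes) != 2L || !(lab %in% m$classes)) {
      stop_contract("model for label '", lab,
                    "' is not a binary present/absent model for that label")
    }
  }
  presence <- NULL
  imgs <- NULL
  for (lab in names(models)) {
    pred <- predict_images(models[[lab]], images)
    imgs <- pred$image
    presence <- cbind(presence, pred$label == lab)
  }
  colnames(presence) <- names(models)
  report <- data.frame(
    image = imgs,
    labels = apply(presence, 1, function(p) {
      paste(names(models)[p], collapse = ",")
    }),
    stringsAsFactors = FALSE
  )
  structure(report, presence = presence,
            class = c("multilabel_report", class(report)))
}
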