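# Haar discrete wavelet transform and the anisotropic 3D texture feature.
#
# The anisotropic feature is built for confocal stacks whose z resolution is
# coarser than x-y: instead of a full (cubic-cost) 3D DWT, the z extent of a
# patch is collapsed into one plane by a Gaussian weight w(zi) that favors
# the middle slices, and a standard multi-level 2D Haar DWT of that plane
# provides the features.  Feature count is therefore quadratic, not cubic,
# in the patch side.
#
# Scaling is orthonormal (1/sqrt(2) filters), so for power-of-two inputs the
# transform conserves energy exactly -- a property the tests rely on.

haar_pad_size <- function(n, levels) as.integer(ceiling(n / 2^levels) * 2^levels)

# one orthonormal Haar analysis level along both axes of an even-sized matrix
haar_level_2d <- function(m) {
  s2 <- sqrt(2)
  n1 <- nrow(m); n2 <- ncol(m)
  o <- seq(1L, n1, 2L); e <- seq(2L, n1, 2L)
  m <- rbind((m[o, , drop = FALSE] + m[e, , drop = FALSE]) / s2,
             (m[o, , drop = FALSE] - m[e, , drop = FALSE]) / s2)
  o <- seq(1L, n2, 2L); e <- seq(2L, n2, 2L)
  cbind((m[, o, drop = FALSE] + m[, e, drop = FALSE]) / s2,
        (m[, o, drop = FALSE] - m[, e, drop = FALSE]) / s2)
}

#' Multi-level 2D Haar wavelet transform
#'
#' Orthonormal Haar decomposition in the standard Mallat layout: each level
#' transforms only the approximation (LL) block of the previous, finer level.
#' Sides that are not a multiple of `2^levels` are padded on the high side up
#' front by edge replication, so every level sees even block sizes and a
#' constant input keeps zero detail coefficients at every geometry; the
#' output has the element count of the padded input.
#'
#' @param plane numeric matrix, indexed `(x, y)`.
#' @param levels number of decomposition levels (dilation scales).
#' @return The coefficient matrix, with attributes `levels` and `orig_dim`.
#' @export
haar_dwt_2d <- function(plane, levels = 2L) {
  plane <- as.matrix(plane)
  if (!is_count(levels)) stop("'levels' must be a positive integer")
  if (2^levels > min(dim(plane))) {
    stop(sprintf("levels = %d exceeds admissible depth for a %d x %d plane",
                 levels, nrow(plane), ncol(plane)))
  }
  pd <- c(haar_pad_size(nrow(plane), levels), haar_pad_size(ncol(plane), levels))
  coef <- plane[
    pmin(seq_len(pd[1]), nrow(plane)),
    pmin(seq_len(pd[2]), ncol(plane)),
    drop = FALSE
  ]
  for (l in seq_len(levels)) {
    b <- pd %/% 2L^(l - 1L)
    coef[seq_len(b[1]), seq_len(b[2])] <-
      haar_level_2d(coef[seq_len(b[1]), seq_len(b[2]), drop = FALSE])
  }
  structure(coef, levels = as.integer(levels), orig_dim = dim(plane))
}

# Subband blocks of a Mallat-layout coefficient matrix.  Returns a list with
# the coarsest LL block first, then per level (coarsest first) LH (low x /
# high y), HL and HH blocks.
haar_subbands <- function(coef, levels = attr(coef, "levels")) {
  pd <- dim(coef)
  out <- list(LL = coef[seq_len(pd[1] %/% 2^levels),
                        seq_len(pd[2] %/% 2^levels), drop = FALSE])
  for (l in seq(levels, 1L)) {
    lo <- pd %/% 2L^l
    hi <- pd %/% 2L^(l - 1L)
    xs_lo <- seq_len(lo[1]); xs_hi <- (lo[1] + 1L):hi[1]
    ys_lo <- seq_len(lo[2]); ys_hi <- (lo[2] + 1L):hi[2]
    out[[sprintf("LH%d", l)]] <- coef[xs_lo, ys_hi, drop = FALSE]
    out[[sprintf("HL%d", l)]] <- coef[xs_hi, ys_lo, drop = FALSE]
    out[[sprintf("HH%d", l)]] <- coef[xs_hi, ys_hi, drop = FALSE]
  }
  out
}

# Fixed flattening: coarsest LL block first, then per level (coarsest level
# first) LH, HL, HH; each block column-major (x fastest).  Saved models
# depend on this order being stable.
flatten_haar <- function(coef, levels = attr(coef, "levels")) {
  bands <- haar_subbands(coef, levels)
  unlist(lapply(names(bands), function(nm) {
    v <- as.vector(bands[[nm]])
    names(v) <- sprintf("%s.%d", nm, seq_along(v))
    v
  }))
}

#' Gaussian z-slice weights
#'
#' Weights for collapsing the `2*rz+1` slices of a patch into one plane:
#' `w(zi)` proportional to `exp(-zi^2 / (2*sigma^2))` for slice offsets
#' `zi = -rz..rz`, normalized to sum to one, so middle slices weigh heavier.
#'
#' @param rz z half-width of the patch.
#' @param sigma spread of the generating Gaussian, in slices; default
#'   `max(rz, 1) / 2`.
#' @return Numeric vector of `2*rz+1` weights summing to 1.
#' @export
z_weights <- function(rz, sigma = max(rz, 1) / 2) {
  if (!is_number(sigma) || sigma <= 0) stop("'sigma' must be positive")
  zi <- seq(-rz, rz)
  w <- exp(-zi^2 / (2 * sigma^2))
  w / sum(w)
}

#' Anisotropic 3D wavelet texture features of a patch
#'
#' The feature of a voxel is computed from its surrounding
#' `(2*rx+1) x (2*ry+1) x (2*rz+1)` patch: slices are collapsed by the
#' Gaussian weights `w(zi)` into a single plane
#' `P(x, y) = sum_zi w(zi) * I(x, y, zi)`, and all coefficients of the
#' `levels`-level orthonormal 2D Haar transform of `P` are returned,
#' flattened in the package's fixed subband order.  The feature length equals
#' the padded patch area, independent of `rz`; `rz = 0` degenerates exactly
#' to the 2D Haar features of the center slice.
#'
#' @param v an [image_volume()]; either the patch itself (when `center` is
#'   `NULL`) or the full volume from which the patch around `center` is
#'   extracted with [extract_patch()] (zero-padded at borders).
#' @param center optional 0-based patch center.
#' @param geometry [patch_geometry()]; required with `center`.
#' @param levels wavelet levels (dilation scales), default 2.
#' @param sigma Gaussian z-weight spread; see [z_weights()].
#' @return Named numeric feature vector.
#' @export
features_aniso_wavelet_3d <- function(v, center = NULL, geometry = NULL,
                                      levels = 2L, sigma = NULL) {
  if (!is.null(center)) {
    if (is.null(geometry)) stop("'geometry' is required when 'center' is given")
    v <- extract_patch(v, center, geometry)
  }
  d <- dim(v)
  if (any(d[1:2] %% 2L == 0L)) {
    stop("patch x/y sides must be odd (2*r+1)")
  }
  rz <- (d[3] - 1L) %/% 2L
  w <- z_weights(rz, sigma %||% max(rz, 1) / 2)
  plane <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) plane <- plane + w[k] * v$voxels[, , k]
  out <- flatten_haar(haar_dwt_2d(plane, levels))
  names(out) <- paste0("aniso3d.", names(out))
  out
}

#' 2D Haar wavelet features of an image
#'
#' Two pooling modes: `"raw"` returns the flattened coefficient matrix (for
#' fixed-size ROI patches, where every sample has the same geometry);
#' `"stats"` returns, per subband and level, the mean and standard deviation
#' of absolute coefficients -- a fixed-length summary
#' (`2 * (3*levels + 1)` values) usable on whole images of varying size.
#'
#' @param v an [image_volume()] with `nz = 1`, or a numeric matrix.
#' @param levels wavelet levels, default 2.
#' @param pooling `"stats"` (default) or `"raw"`.
#' @return Named numeric feature vector.
#' @export
features_haar_2d <- function(v, levels = 2L, pooling = c("stats", "raw")) {
  pooling <- match.arg(pooling)
  plane <- if (inherits(v, "image_volume")) {
    if (!is_2d(v)) stop("features_haar_2d expects a 2D image (nz = 1)")
    v$voxels[, , 1]
  } else {
    as.matrix(v)
  }
  coef <- haar_dwt_2d(plane, levels)
  if (pooling == "raw") {
    out <- flatten_haar(coef)
    names(out) <- paste0("haar2d.", names(out))
    return(out)
  }
  bands <- haar_subbands(coef)
  out <- unlist(lapply(names(bands), function(nm) {
    a <- abs(as.vector(bands[[nm]]))
    stats::setNames(c(mean(a), stats::sd(a)),
                    paste0("haar2d.", nm, c(".mean", ".sd")))
  }))
  out[is.na(out)] <- 0 # sd of a single coefficient
  out
}
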