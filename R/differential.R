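# Gaussian-derivative, Laplacian and Hessian features.
#
# All derivatives are computed by separable correlation with sampled
# Gaussian-derivative kernels.  Kernels are normalized so that polynomial
# inputs give exact responses (a ramp has first derivative 1, a parabola t^2
# has second derivative 2), and borders use edge replication.  Hessian
# eigenvalues are suited to detecting tube-like (neuronal) structures: on a
# ridge one eigenvalue dominates the other(s) in magnitude.

gaussian_kernel <- function(sigma, order = 0L) {
  r <- max(1L, ceiling(3 * sigma))
  t <- seq(-r, r)
  g <- exp(-t^2 / (2 * sigma^2))
  switch(as.character(order),
    "0" = g / sum(g),
    "1" = {
      k <- t * g
      k / sum(t * k) # response to input t is exactly 1
    },
    "2" = {
      k <- (t^2 - sum(t^2 * g) / sum(g)) * g # zero mean on constants
      2 * k / sum(t^2 * k) # response to input t^2 is exactly 2
    },
    stop("derivative order must be 0, 1 or 2")
  )
}

# correlate a 3D array with a 1D kernel along one axis, replicating edges
conv_axis <- function(arr, k, axis) {
  d <- dim(arr)
  r <- (length(k) - 1L) %/% 2L
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- dim(a)[1]
  m <- matrix(a, nrow = n)
  pad_idx <- c(rep(1L, r), seq_len(n), rep(n, r))
  mp <- m[pad_idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  a <- array(out, dim(a))
  aperm(a, order(perm))
}

gaussian_derivative <- function(vox, sigma, orders) {
  # orders = c(ox, oy, oz); axes with order 0 get plain Gaussian smoothing
  d <- dim(vox)
  for (axis in 1:3) {
    if (d[axis] == 1L) next
    vox <- conv_axis(vox, gaussian_kernel(sigma, orders[axis]), axis)
  }
  vox
}

# eigenvalues of symmetric 2x2 / 3x3 matrices, vectorized over voxels,
# sorted descending per voxel
sym_eigen_2d <- function(hxx, hyy, hxy) {
  tr <- (hxx + hyy) / 2
  disc <- sqrt(pmax(((hxx - hyy) / 2)^2 + hxy^2, 0))
  list(tr + disc, tr - disc)
}

sym_eigen_3d <- function(a11, a22, a33, a12, a13, a23) {
  # analytic (trigonometric) eigenvalues of a symmetric 3x3 matrix
  q <- (a11 + a22 + a33) / 3
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  p2 <- (b11^2 + b22^2 + b33^2 + 2 * (a12^2 + a13^2 + a23^2)) / 6
  p <- sqrt(pmax(p2, 0))
  detB <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  list(e1, e2, e3)
}

#' Gaussian-derivative, Laplacian and Hessian features
#'
#' Per scale `sigma`, computes Gaussian-smoothed first derivatives along each
#' axis, the Laplacian (sum of pure second derivatives) and the eigenvalues
#' of the Hessian matrix (sorted descending per voxel).  Two pooling modes:
#' `"at-center"` returns the map values at one coordinate (ROI mode);
#' `"image-stats"` returns mean and standard deviation of each map
#' (whole-image mode).  Feature length is a pure function of the scales, the
#' dimensionality and the pooling mode.
#'
#' @param v an [image_volume()].
#' @param scales positive Gaussian scales, in voxels.
#' @param pooling `"image-stats"` (default) or `"at-center"`.
#' @param center 0-based coordinate for `"at-center"` pooling.
#' @return Named numeric feature vector.
#' @export
differential_features <- function(v, scales = c(1, 2),
                                  pooling = c("image-stats", "at-center"),
                                  center = NULL) {
  pooling <- match.arg(pooling)
  d <- dim(v)
  ndim <- if (d[3] > 1L) 3L else 2L
  if (any(2 * ceiling(3 * max(scales)) + 1 > d[seq_len(ndim)])) {
    stop("largest Gaussian kernel exceeds the image size")
  }
  out <- numeric(0)
  for (s in scales) {
    maps <- list()
    maps$dx <- gaussian_derivative(v$voxels, s, c(1, 0, 0))
    maps$dy <- gaussian_derivative(v$voxels, s, c(0, 1, 0))
    if (ndim == 3L) maps$dz <- gaussian_derivative(v$voxels, s, c(0, 0, 1))
    hxx <- gaussian_derivative(v$voxels, s, c(2, 0, 0))
    hyy <- gaussian_derivative(v$voxels, s, c(0, 2, 0))
    hxy <- gaussian_derivative(v$voxels, s, c(1, 1, 0))
    if (ndim == 2L) {
      maps$laplacian <- hxx + hyy
      ev <- sym_eigen_2d(hxx, hyy, hxy)
    } else {
      hzz <- gaussian_derivative(v$voxels, s, c(0, 0, 2))
      hxz <- gaussian_derivative(v$voxels, s, c(1, 0, 1))
      hyz <- gaussian_derivative(v$voxels, s, c(0, 1, 1))
      maps$laplacian <- hxx + hyy + hzz
      ev <- sym_eigen_3d(hxx, hyy, hzz, hxy, hxz, hyz)
    }
    for (i in seq_along(ev)) maps[[sprintf("hess_ev%d", i)]] <- ev[[i]]
    for (nm in names(maps)) {
      tag <- sprintf("diff.s%g.%s", s, nm)
      if (pooling == "at-center") {
        if (is.null(center)) stop("'center' is required for at-center pooling")
        co <- if (is.data.frame(center)) {
          c(center$x[1], center$y[1], center$z[1])
        } else {
          center
        }
        val <- maps[[nm]][co[1] + 1L, co[2] + 1L, co[3] + 1L]
        out <- c(out, stats::setNames(val, tag))
      } else {
        out <- c(out, stats::setNames(
          c(mean(maps[[nm]]), stats::sd(maps[[nm]])),
          paste0(tag, c(".mean", ".sd"))
        ))
      }
    }
  }
  out
}
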