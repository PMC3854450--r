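# Moment-invariant extractors: 2D Hu (8 values), a 3D extension (8 values)
# and Zernike moment magnitudes.  All moments are intensity-weighted (raw
# gray values, not binarized masks).

central_moments_2d <- function(img, max_order = 3L) {
  d <- dim(img)
  m00 <- sum(img)
  if (m00 <= 0) stop("degenerate input: zero total intensity")
  xs <- seq_len(d[1]) - 1; ys <- seq_len(d[2]) - 1
  cx <- sum(xs * rowSums(img)) / m00
  cy <- sum(ys * colSums(img)) / m00
  dx <- xs - cx; dy <- ys - cy
  mu <- matrix(0, max_order + 1L, max_order + 1L)
  for (p in 0:max_order) {
    for (q in 0:max_order) {
      if (p + q > max_order) next
      mu[p + 1L, q + 1L] <- sum(outer(dx^p, dy^q) * img)
    }
  }
  mu
}

# scale-normalized central moments eta_pq = mu_pq / mu_00^(1 + (p+q)/2)
eta_2d <- function(mu) {
  eta <- mu
  for (p in 0:(nrow(mu) - 1L)) {
    for (q in 0:(ncol(mu) - 1L)) {
      eta[p + 1L, q + 1L] <- mu[p + 1L, q + 1L] / mu[1L, 1L]^(1 + (p + q) / 2)
    }
  }
  eta
}

#' 2D Hu moment invariants (8 values)
#'
#' The seven classical Hu invariants computed from scale-normalized central
#' moments of the gray-value image, plus Flusser's additional third-order
#' skew invariant as the documented 8th value:
#' `I8 = eta11*((eta30+eta12)^2 - (eta03+eta21)^2)
#'       - (eta20-eta02)*(eta30+eta12)*(eta03+eta21)`.
#' All eight are invariant to translation, scaling and rotation.
#'
#' @param img numeric matrix `(x, y)` or a 2D [image_volume()].
#' @return Named numeric vector of length 8.
#' @export
hu_moments_2d <- function(img) {
  if (inherits(img, "image_volume")) {
    if (!is_2d(img)) stop("hu_moments_2d expects a 2D image")
    img <- img$voxels[, , 1]
  }
  e <- eta_2d(central_moments_2d(img))
  n20 <- e[3, 1]; n02 <- e[1, 3]; n11 <- e[2, 2]
  n30 <- e[4, 1]; n03 <- e[1, 4]; n21 <- e[3, 2]; n12 <- e[2, 3]
  a <- n30 + n12; b <- n21 + n03
  c1 <- n30 - 3 * n12; c2 <- 3 * n21 - n03
  out <- c(
    hu1 = n20 + n02,
    hu2 = (n20 - n02)^2 + 4 * n11^2,
    hu3 = c1^2 + c2^2,
    hu4 = a^2 + b^2,
    hu5 = c1 * a * (a^2 - 3 * b^2) + c2 * b * (3 * a^2 - b^2),
    hu6 = (n20 - n02) * (a^2 - b^2) + 4 * n11 * a * b,
    hu7 = c2 * a * (a^2 - 3 * b^2) - c1 * b * (3 * a^2 - b^2),
    hu8 = n11 * (a^2 - b^2) - (n20 - n02) * a * b
  )
  out
}

central_moments_3d <- function(vox) {
  d <- dim(vox)
  m000 <- sum(vox)
  if (m000 <= 0) stop("degenerate input: zero total intensity")
  xs <- seq_len(d[1]) - 1; ys <- seq_len(d[2]) - 1; zs <- seq_len(d[3]) - 1
  cx <- sum(xs * apply(vox, 1, sum)) / m000
  cy <- sum(ys * apply(vox, 2, sum)) / m000
  cz <- sum(zs * apply(vox, 3, sum)) / m000
  dx <- xs - cx; dy <- ys - cy; dz <- zs - cz
  mu <- function(p, q, r) {
    wx <- dx^p; wy <- dy^q; wz <- dz^r
    acc <- 0
    for (k in seq_len(d[3])) {
      acc <- acc + wz[k] * sum(outer(wx, wy) * vox[, , k])
    }
    acc
  }
  list(m000 = m000, mu = mu)
}

#' 3D Hu-style moment invariants (8 values)
#'
#' A fixed set of eight translation- and scale-invariant summaries of the 3D
#' gray-value distribution, built from central moments up to order 3
#' normalized by `eta_pqr = mu_pqr / mu_000^(1 + (p+q+r)/3)`:
#' the three classical second-order rotation invariants
#' `J1 = eta200+eta020+eta002`,
#' `J2 = eta200*eta020 + eta020*eta002 + eta002*eta200 - eta110^2 - eta101^2 - eta011^2`,
#' `J3 = det` of the normalized second-moment matrix, plus five documented
#' central-moment magnitudes: the off-diagonal energy
#' `eta110^2+eta101^2+eta011^2`, the third-order energies
#' `sum eta_(3,0,0)-type^2`, `sum eta_(2,1,0)-type^2`, `eta111^2`, and the
#' squared norm of the vector `(eta300+eta120+eta102, eta030+eta210+eta012,
#' eta003+eta201+eta021)`.  `J1..J3` are additionally invariant to rotation
#' (hence to axis permutation).
#'
#' @param v an [image_volume()] or 3D numeric array.
#' @return Named numeric vector of length 8.
#' @export
hu_moments_3d <- function(v) {
  vox <- if (inherits(v, "image_volume")) v$voxels else v
  cm <- central_moments_3d(vox)
  eta <- function(p, q, r) cm$mu(p, q, r) / cm$m000^(1 + (p + q + r) / 3)
  e200 <- eta(2, 0, 0); e020 <- eta(0, 2, 0); e002 <- eta(0, 0, 2)
  e110 <- eta(1, 1, 0); e101 <- eta(1, 0, 1); e011 <- eta(0, 1, 1)
  e300 <- eta(3, 0, 0); e030 <- eta(0, 3, 0); e003 <- eta(0, 0, 3)
  e210 <- eta(2, 1, 0); e201 <- eta(2, 0, 1); e120 <- eta(1, 2, 0)
  e021 <- eta(0, 2, 1); e102 <- eta(1, 0, 2); e012 <- eta(0, 1, 2)
  e111 <- eta(1, 1, 1)
  g1 <- e300 + e120 + e102
  g2 <- e030 + e210 + e012
  g3 <- e003 + e201 + e021
  c(
    J1 = e200 + e020 + e002,
    J2 = e200 * e020 + e020 * e002 + e002 * e200 - e110^2 - e101^2 - e011^2,
    J3 = e200 * e020 * e002 + 2 * e110 * e101 * e011 -
      e200 * e011^2 - e020 * e101^2 - e002 * e110^2,
    H4 = e110^2 + e101^2 + e011^2,
    H5 = e300^2 + e030^2 + e003^2,
    H6 = e210^2 + e201^2 + e120^2 + e021^2 + e102^2 + e012^2,
    H7 = e111^2,
    H8 = g1^2 + g2^2 + g3^2
  )
}

# (n, m) index pairs in enumeration order: n ascending; for each n, m in
# {n mod 2, ..., n} step 2 (m >= 0, n - m even), ascending.
zernike_orders <- function(count) {
  n <- 0L
  out <- matrix(0L, 0L, 2L)
  while (nrow(out) < count) {
    ms <- seq(n %% 2L, n, by = 2L)
    out <- rbind(out, cbind(n, ms))
    n <- n + 1L
  }
  out[seq_len(count), , drop = FALSE]
}

# radial polynomial R_nm(rho)
zernike_radial <- function(n, m, rho) {
  s_max <- (n - m) %/% 2L
  acc <- 0
  for (s in 0:s_max) {
    acc <- acc + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s)) *
      rho^(n - 2 * s)
  }
  acc
}

#' Zernike moment magnitudes
#'
#' The image is mapped onto the unit disk about its intensity centroid, with
#' radius equal to the largest centroid-to-corner distance (so every pixel
#' lies inside the disk).  Moments `A_nm` are the projections onto the
#' complex Zernike polynomials; magnitudes `|A_nm|` are rotation-invariant
#' and are returned for the first `count` index pairs in `(n, m)` order.
#'
#' @param img numeric matrix `(x, y)` or a 2D [image_volume()].
#' @param count number of moments, default 20.
#' @return Named numeric vector of length `count`.
#' @export
zernike_moments <- function(img, count = 20L) {
  if (inherits(img, "image_volume")) {
    if (!is_2d(img)) stop("zernike_moments expects a 2D image")
    img <- img$voxels[, , 1]
  }
  if (!is_count(count)) stop("'count' must be a positive integer")
  d <- dim(img)
  tot <- sum(img)
  if (tot <= 0) stop("degenerate input: zero total intensity")
  xs <- seq_len(d[1]) - 1; ys <- seq_len(d[2]) - 1
  cx <- sum(xs * rowSums(img)) / tot
  cy <- sum(ys * colSums(img)) / tot
  corners <- expand.grid(x = c(0, d[1] - 1), y = c(0, d[2] - 1))
  R <- max(sqrt((corners$x - cx)^2 + (corners$y - cy)^2))
  gx <- matrix(xs - cx, d[1], d[2]) / R
  gy <- matrix(ys - cy, d[1], d[2], byrow = TRUE) / R
  rho <- sqrt(gx^2 + gy^2)
  theta <- atan2(gy, gx)
  orders <- zernike_orders(count)
  out <- numeric(count)
  for (i in seq_len(count)) {
    n <- orders[i, 1]; m <- orders[i, 2]
    rad <- zernike_radial(n, m, rho)
    re <- sum(img * rad * cos(m * theta))
    im <- sum(img * rad * sin(m * theta))
    out[i] <- (n + 1) / pi * sqrt(re^2 + im^2)
  }
  names(out) <- sprintf("zernike.n%dm%d", orders[, 1], orders[, 2])
  out
}
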