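# Hu and Zernike moment invariants.

# bilinear rotation about the image center, used to probe rotation invariance
rotate_image <- function(img, degrees) {
  th <- degrees * pi / 180
  d <- dim(img)
  ctr <- (d - 1) / 2
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      # inverse map of the output pixel
      dx <- i - 1 - ctr[1]; dy <- j - 1 - ctr[2]
      sx <- cos(th) * dx + sin(th) * dy + ctr[1]
      sy <- -sin(th) * dx + cos(th) * dy + ctr[2]
      x0 <- floor(sx); y0 <- floor(sy)
      if (x0 < 0 || y0 < 0 || x0 >= d[1] - 1 || y0 >= d[2] - 1) next
      fx <- sx - x0; fy <- sy - y0
      out[i, j] <- (1 - fx) * (1 - fy) * img[x0 + 1, y0 + 1] +
        fx * (1 - fy) * img[x0 + 2, y0 + 1] +
        (1 - fx) * fy * img[x0 + 1, y0 + 2] +
        fx * fy * img[x0 + 2, y0 + 2]
    }
  }
  out
}

# smooth blob test image, comfortably inside the frame
blob_image <- function(n = 48, cx = NULL, cy = NULL, sigma = 6, seed = 1) {
  cx <- cx %||% (n - 1) / 2; cy <- cy %||% (n - 1) / 2
  xs <- seq_len(n) - 1
  g <- outer(exp(-(xs - cx)^2 / (2 * sigma^2)), exp(-(xs - cy)^2 / (2 * sigma^2)))
  withr::with_seed(seed, 100 * g + 100 * outer(
    exp(-(xs - cx - 4)^2 / (2 * (sigma / 2)^2)),
    exp(-(xs - cy + 3)^2 / (2 * (sigma / 2)^2))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("2D Hu invariants are translation and rotation invariant", {
  img <- matrix(0, 48, 48)
  img[10:20, 8:22] <- blob_image(16, 7, 7, 3)[1:11, 1:15]
  shifted <- matrix(0, 48, 48)
  shifted[15:25, 11:25] <- img[10:20, 8:22] # translated by (5, 3)
  expect_equal(hu_moments_2d(img), hu_moments_2d(shifted), tolerance = 1e-9)

  rot90 <- t(img)[ncol(img):1, ] # exact 90-degree rotation
  expect_equal(abs(hu_moments_2d(img)), abs(hu_moments_2d(rot90)),
               tolerance = 1e-6)
})

test_that("2D Hu invariants survive scale doubling by pixel replication", {
  img <- blob_image(48, sigma = 9)
  doubled <- img[rep(seq_len(48), each = 2), rep(seq_len(48), each = 2)]
  expect_equal(hu_moments_2d(img), hu_moments_2d(doubled), tolerance = 1e-3)
})

test_that("2D Hu invariants match a from-scratch moment oracle", {
  img <- rand_matrix(5, 5, seed = 30)
  # independent oracle: raw double sums for the normalized central moments
  # and the invariant formulas
  m <- function(p, q) {
    acc <- 0
    for (i in 0:4) for (j in 0:4) acc <- acc + i^p * j^q * img[i + 1, j + 1]
    acc
  }
  cx <- m(1, 0) / m(0, 0); cy <- m(0, 1) / m(0, 0)
  mu <- function(p, q) {
    acc <- 0
    for (i in 0:4) for (j in 0:4) {
      acc <- acc + (i - cx)^p * (j - cy)^q * img[i + 1, j + 1]
    }
    acc
  }
  eta <- function(p, q) mu(p, q) / mu(0, 0)^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  a <- n30 + n12; b <- n21 + n03
  oracle <- c(
    n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    a^2 + b^2,
    (n30 - 3 * n12) * a * (a^2 - 3 * b^2) + (3 * n21 - n03) * b * (3 * a^2 - b^2),
    (n20 - n02) * (a^2 - b^2) + 4 * n11 * a * b,
    (3 * n21 - n03) * a * (a^2 - 3 * b^2) - (n30 - 3 * n12) * b * (3 * a^2 - b^2),
    n11 * (a^2 - b^2) - (n20 - n02) * a * b
  )
  expect_equal(unname(hu_moments_2d(img)), oracle, tolerance = 1e-12)
})

test_that("3D invariants are translation invariant and J's survive axis swaps", {
  vol <- array(0, c(24, 24, 12))
  withr::with_seed(31, {
    core <- array(runif(5 * 4 * 3) * 10, c(5, 4, 3))
  })
  vol[6:10, 7:10, 4:6] <- core
  shifted <- array(0, c(24, 24, 12))
  shifted[8:12, 8:11, 5:7] <- core # translated by (2, 1, 1)
  expect_equal(hu_moments_3d(vol), hu_moments_3d(shifted), tolerance = 1e-9)

  swapped <- aperm(vol, c(2, 1, 3)) # x <-> y
  expect_equal(hu_moments_3d(vol)[c("J1", "J2", "J3")],
               hu_moments_3d(swapped)[c("J1", "J2", "J3")], tolerance = 1e-9)
})

test_that("3D invariants match a triple-sum oracle on a toy volume", {
  vol <- withr::with_seed(32, array(runif(27) * 5, c(3, 3, 3)))
  mu <- function(p, q, r, cx, cy, cz) {
    acc <- 0
    for (i in 0:2) for (j in 0:2) for (k in 0:2) {
      acc <- acc + (i - cx)^p * (j - cy)^q * (k - cz)^r * vol[i + 1, j + 1, k + 1]
    }
    acc
  }
  m000 <- mu(0, 0, 0, 0, 0, 0)
  cx <- mu(1, 0, 0, 0, 0, 0) / m000
  cy <- mu(0, 1, 0, 0, 0, 0) / m000
  cz <- mu(0, 0, 1, 0, 0, 0) / m000
  eta <- function(p, q, r) mu(p, q, r, cx, cy, cz) / m000^(1 + (p + q + r) / 3)
  got <- hu_moments_3d(vol)
  expect_equal(unname(got["J1"]), eta(2, 0, 0) + eta(0, 2, 0) + eta(0, 0, 2),
               tolerance = 1e-12)
  expect_equal(unname(got["H4"]),
               eta(1, 1, 0)^2 + eta(1, 0, 1)^2 + eta(0, 1, 1)^2,
               tolerance = 1e-12)
  expect_equal(unname(got["H7"]), eta(1, 1, 1)^2, tolerance = 1e-12)
  expect_equal(unname(got["H5"]),
               eta(3, 0, 0)^2 + eta(0, 3, 0)^2 + eta(0, 0, 3)^2,
               tolerance = 1e-12)
})

test_that("3D invariants survive scale doubling by voxel replication", {
  # smooth, spatially extended blobs: replication is only approximately a
  # scale change (half-voxel offsets), with bias ~ 1/(16*sigma^2) on the
  # second-order invariants, so wide Gaussians keep it below 1e-3
  n <- 72; xs <- seq_len(n) - 1
  g1 <- outer(outer(exp(-(xs - 34)^2 / (2 * 18^2)),
                    exp(-(xs - 37)^2 / (2 * 16^2))),
              exp(-(xs - 33)^2 / (2 * 17^2)))
  g2 <- outer(outer(exp(-(xs - 42)^2 / (2 * 12^2)),
                    exp(-(xs - 30)^2 / (2 * 13^2))),
              exp(-(xs - 39)^2 / (2 * 11^2)))
  vol <- 100 * g1 + 60 * g2
  doubled <- vol[rep(1:n, each = 2), rep(1:n, each = 2), rep(1:n, each = 2)]
  a <- hu_moments_3d(vol); b <- hu_moments_3d(doubled)
  expect_true(all(abs(b - a) <= 1e-3 * abs(a)))
})

test_that("2D scale doubling holds per component as well", {
  img <- blob_image(48, sigma = 9)
  doubled <- img[rep(seq_len(48), each = 2), rep(seq_len(48), each = 2)]
  a <- hu_moments_2d(img); b <- hu_moments_2d(doubled)
  expect_true(all(abs(b - a) <= 1e-3 * abs(a)))
})

test_that("Zernike magnitudes have fixed length and angular symmetry", {
  img <- blob_image(32)
  expect_length(zernike_moments(img), 20L)
  expect_length(zernike_moments(img, 12L), 12L)

  # radially symmetric image: angular moments vanish.  On a square pixel
  # grid the cancellation is exact except for m divisible by 4 (the grid's
  # own symmetry), which only vanishes up to discretization.
  n <- 41
  ys <- seq_len(n) - 1 - (n - 1) / 2
  radial <- outer(exp(-ys^2 / (2 * 49)), exp(-ys^2 / (2 * 49)))
  z <- zernike_moments(radial)
  m_of <- as.integer(sub(".*m", "", names(z)))
  expect_true(all(z[m_of %% 4 != 0 & m_of != 0] < 1e-9 * max(z)))
  expect_true(all(z[m_of %% 4 == 0 & m_of != 0] < 1e-2 * max(z)))
})

test_that("Zernike magnitudes are rotation invariant under resampling", {
  n <- 64; xs <- seq_len(n) - 1
  img <- 100 * outer(exp(-(xs - 31.5)^2 / (2 * 100)),
                     exp(-(xs - 31.5)^2 / (2 * 64))) +
    60 * outer(exp(-(xs - 38)^2 / (2 * 25)), exp(-(xs - 26)^2 / (2 * 25)))
  rot <- rotate_image(img, 37)
  z0 <- zernike_moments(img)
  z1 <- zernike_moments(rot)
  # bilinear resampling perturbs near-zero magnitudes arbitrarily in relative
  # terms; the invariance claim is checked on non-negligible moments
  keep <- z0 > 0.01 * max(z0)
  expect_lt(max(abs(z1[keep] - z0[keep]) / z0[keep]), 0.02)
})

test_that("degenerate zero-intensity inputs are rejected", {
  expect_error(hu_moments_2d(matrix(0, 5, 5)), "degenerate")
  expect_error(hu_moments_3d(array(0, c(3, 3, 3))), "degenerate")
  expect_error(zernike_moments(matrix(0, 5, 5)), "degenerate")
})
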