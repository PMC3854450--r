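# Shared fixture builders.  All fixtures are generated in code at test time;
# nothing binary lives in the repository.

rand_volume <- function(nx, ny, nz = 1L, seed = 1L, scale = 10) {
  withr::with_seed(seed, image_volume(array(runif(nx * ny * nz) * scale,
                                            c(nx, ny, nz))))
}

rand_matrix <- function(n1, n2, seed = 1L, scale = 10) {
  withr::with_seed(seed, matrix(runif(n1 * n2) * scale, n1, n2))
}

# directory tree of tiny distinct images: classes x images-per-class
make_tree <- function(root, classes = c("classA", "classB"), per_class = 3L,
                      size = 8L, seed = 1L) {
  k <- 0L
  for (cls in classes) {
    dir.create(file.path(root, cls), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(per_class)) {
      k <- k + 1L
      v <- rand_volume(size, size, seed = seed + k, scale = 100)
      write_image_volume(v, file.path(root, cls, sprintf("img%02d.tif", i)))
    }
  }
  root
}

# well-separated 2-blob feature set for classifier tests
blob_features <- function(n_per_class = 40L, gap = 10, sd = 1, seed = 1L) {
  withr::with_seed(seed, {
    x <- rbind(
      cbind(rnorm(n_per_class, 0, sd), rnorm(n_per_class, 0, sd)),
      cbind(rnorm(n_per_class, gap, sd), rnorm(n_per_class, gap, sd))
    )
    colnames(x) <- c("fA", "fB")
    list(x = x, labels = rep(c("lo", "hi"), each = n_per_class))
  })
}

# explicit orthonormal Mallat Haar analysis operator for an n x n plane with
# `levels` levels, as a (n^2 x n^2) matrix acting on vec(plane) --
# independent of the package's transform code
haar_oracle_matrix <- function(n, levels) {
  single_level_1d <- function(m) {
    # m even: averaging rows then difference rows, orthonormal
    h <- matrix(0, m, m)
    for (i in seq_len(m / 2)) {
      h[i, 2 * i - 1] <- 1 / sqrt(2); h[i, 2 * i] <- 1 / sqrt(2)
      h[m / 2 + i, 2 * i - 1] <- 1 / sqrt(2); h[m / 2 + i, 2 * i] <- -1 / sqrt(2)
    }
    h
  }
  lin <- function(i, j) (j - 1) * n + i # column-major vec index
  total <- diag(n * n)
  for (l in seq_len(levels)) {
    b <- n / 2^(l - 1)
    h1 <- single_level_1d(b)
    step <- diag(n * n)
    # inside the leading b x b block: out(i,j) = sum h1[i,k] h1[j,m] X[k,m];
    # everything outside the block (earlier detail strips) is untouched
    for (i in 1:b) for (j in 1:b) {
      row <- numeric(n * n)
      for (k in 1:b) for (m in 1:b) row[lin(k, m)] <- h1[i, k] * h1[j, m]
      step[lin(i, j), ] <- row
    }
    total <- step %*% total
  }
  total
}

# flatten a Mallat coefficient matrix in the package's documented order,
# implemented independently (LL coarsest first, then per level LH, HL, HH)
flatten_oracle <- function(coef, n, levels) {
  out <- as.vector(coef[seq_len(n / 2^levels), seq_len(n / 2^levels)])
  for (l in seq(levels, 1)) {
    lo <- n / 2^l; hi <- n / 2^(l - 1)
    out <- c(out,
             as.vector(coef[1:lo, (lo + 1):hi]),
             as.vector(coef[(lo + 1):hi, 1:lo]),
             as.vector(coef[(lo + 1):hi, (lo + 1):hi]))
  }
  out
}
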