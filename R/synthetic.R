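# Deterministic synthetic fixtures emulating the kinds of data the toolkit
# targets: 3D nucleus-like blob volumes with ground-truth centers (counting),
# two-class texture sets (chain comparison), and tube/ridge images (Hessian
# features).  Generators are pure functions of their spec including the seed,
# and write the exact external formats (TIFF, marker files, directory trees)
# so the IO paths are exercised rather than bypassed.

#' Blob volume specification
#'
#' Defaults emulate a confocal stack of fluorescently labeled cell nuclei:
#' anisotropic Gaussian blobs (z spread smaller in voxels, mirroring coarser
#' z sampling) on a dark noisy background, well separated so each blob is
#' resolvable.
#'
#' @param nx,ny,nz volume size, default 64 x 64 x 16.
#' @param n_blobs number of blobs, default 20.
#' @param sigma_xy,sigma_z Gaussian spreads in voxels (defaults 2.5 and 1.5).
#' @param peak blob peak intensity, default 180.
#' @param noise_sigma background Gaussian noise s.d., default 5 (clipped at 0).
#' @param min_separation minimum center distance, default `4 * sigma_xy`.
#' @param seed RNG seed.
#' @return An object of class `blob_volume_spec`.
#' @export
blob_volume_spec <- function(nx = 64L, ny = 64L, nz = 16L, n_blobs = 20L,
                             sigma_xy = 2.5, sigma_z = 1.5, peak = 180,
                             noise_sigma = 5, min_separation = 4 * sigma_xy,
                             seed = 1L) {
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
         n_blobs = as.integer(n_blobs), sigma_xy = sigma_xy, sigma_z = sigma_z,
         peak = peak, noise_sigma = noise_sigma,
         min_separation = min_separation, seed = as.integer(seed)),
    class = "blob_volume_spec"
  )
}

#' Generate a blob volume with ground-truth centers
#'
#' Sum of anisotropic Gaussian blobs plus clipped Gaussian noise.  Centers
#' are drawn by rejection sampling to honor the minimum separation; if the
#' requested count cannot be placed the generation errors out rather than
#' silently crowding blobs.
#'
#' @param spec a [blob_volume_spec()].
#' @return A list with `volume` (an [image_volume()]) and `centers`
#'   (a [coordinates()] data frame of exact blob centers).
#' @export
gen_blob_volume <- function(spec) {
  withr::with_seed(spec$seed, {
    margin_xy <- ceiling(3 * spec$sigma_xy)
    margin_z <- ceiling(2 * spec$sigma_z)
    centers <- matrix(0, 0, 3)
    tries <- 0L
    while (nrow(centers) < spec$n_blobs) {
      tries <- tries + 1L
      if (tries > 20000L) {
        stop("cannot place ", spec$n_blobs, " blobs at separation ",
             spec$min_separation, " in a ", spec$nx, "x", spec$ny, "x",
             spec$nz, " volume")
      }
      # an unlucky early placement can make the remainder infeasible;
      # periodically restart the whole configuration
      if (tries %% 2000L == 0L) centers <- centers[0, , drop = FALSE]
      cand <- c(
        sample(margin_xy:(spec$nx - 1L - margin_xy), 1L),
        sample(margin_xy:(spec$ny - 1L - margin_xy), 1L),
        sample(margin_z:(spec$nz - 1L - margin_z), 1L)
      )
      if (nrow(centers) > 0L) {
        d <- sqrt(colSums((t(centers) - cand)^2))
        if (min(d) < spec$min_separation) next
      }
      centers <- rbind(centers, cand)
    }
    vox <- array(0, c(spec$nx, spec$ny, spec$nz))
    rx <- ceiling(4 * spec$sigma_xy)
    rz <- ceiling(4 * spec$sigma_z)
    for (i in seq_len(nrow(centers))) {
      c0 <- centers[i, ]
      xs <- max(0, c0[1] - rx):min(spec$nx - 1L, c0[1] + rx)
      ys <- max(0, c0[2] - rx):min(spec$ny - 1L, c0[2] + rx)
      zs <- max(0, c0[3] - rz):min(spec$nz - 1L, c0[3] + rz)
      gx <- exp(-(xs - c0[1])^2 / (2 * spec$sigma_xy^2))
      gy <- exp(-(ys - c0[2])^2 / (2 * spec$sigma_xy^2))
      gz <- exp(-(zs - c0[3])^2 / (2 * spec$sigma_z^2))
      blob <- spec$peak * outer(outer(gx, gy), gz)
      vox[xs + 1L, ys + 1L, zs + 1L] <- vox[xs + 1L, ys + 1L, zs + 1L] + blob
    }
    noise <- array(stats::rnorm(length(vox), 0, spec$noise_sigma), dim(vox))
    vox <- pmax(vox + noise, 0)
    list(
      volume = image_volume(vox, channel = "all"),
      centers = coordinates(centers[, 1], centers[, 2], centers[, 3])
    )
  })
}

#' Texture set specification
#'
#' Two classes of sinusoid-modulated noise textures differing in spatial
#' frequency.  The `"easy"` preset keeps noise low enough that the classes
#' are guaranteed separable by Haar subband statistics (asserted at
#' generation time); `"hard"` adds heavy noise.
#'
#' @param per_class images per class, default 10.
#' @param size square image side, default 32.
#' @param freq_low,freq_high class frequencies in cycles per image (defaults
#'   2 and 8).
#' @param separation `"easy"` (noise s.d. 2, fixed sinusoid phase: images in
#'   a class differ by noise only) or `"hard"` (noise s.d. 40 plus uniform
#'   random phase per image).
#' @param seed RNG seed.
#' @return An object of class `texture_set_spec`.
#' @export
texture_set_spec <- function(per_class = 10L, size = 32L, freq_low = 2,
                             freq_high = 8, separation = c("easy", "hard"),
                             seed = 1L) {
  separation <- match.arg(separation)
  structure(
    list(per_class = as.integer(per_class), size = as.integer(size),
         freq_low = freq_low, freq_high = freq_high, separation = separation,
         noise_sigma = if (separation == "easy") 2 else 40,
         seed = as.integer(seed)),
    class = "texture_set_spec"
  )
}

texture_image <- function(size, freq, phase, noise_sigma) {
  xs <- seq_len(size) - 1
  pattern <- 60 * (1 + sin(2 * pi * freq * xs / size + phase))
  img <- matrix(pattern, size, size)
  img + matrix(abs(stats::rnorm(size^2, 0, noise_sigma)), size, size)
}

#' Generate a two-class texture set as a directory tree
#'
#' Writes `class_low/` and `class_high/` TIFFs under `dir` (loadable with
#' [load_directory_tree()]).  For the `"easy"` preset the separation
#' guarantee -- inter-class distance of mean Haar-stat feature vectors more
#' than 10x the intra-class spread -- is asserted at generation time.
#'
#' @param spec a [texture_set_spec()].
#' @param dir output directory.
#' @return The `labeled_image_set` loaded back from the written tree.
#' @export
gen_texture_set <- function(spec, dir) {
  withr::with_seed(spec$seed, {
    for (cls in c("low", "high")) {
      sub <- file.path(dir, paste0("class_", cls))
      dir.create(sub, showWarnings = FALSE, recursive = TRUE)
      freq <- if (cls == "low") spec$freq_low else spec$freq_high
      for (i in seq_len(spec$per_class)) {
        phase <- if (spec$separation == "easy") 0 else stats::runif(1, 0, 2 * pi)
        img <- texture_image(spec$size, freq, phase, spec$noise_sigma)
        write_image_volume(image_volume(img),
                           file.path(sub, sprintf("tex_%02d.tif", i)))
      }
    }
  })
  set <- load_directory_tree(dir)
  if (spec$separation == "easy") {
    fs <- featurize_set(list(extractor_spec("haar2d", levels = 2L)), set)
    assert_separation(fs$features, fs$labels)
  }
  set
}

# easy-preset guarantee: distance between class feature centroids > 10x the
# maximum intra-class RMS distance to its centroid
assert_separation <- function(x, labels) {
  classes <- unique(labels)
  mu <- lapply(classes, function(c) colMeans(x[labels == c, , drop = FALSE]))
  spread <- vapply(seq_along(classes), function(i) {
    xc <- x[labels == classes[i], , drop = FALSE]
    sqrt(mean(rowSums(sweep(xc, 2, mu[[i]])^2)))
  }, 1)
  gap <- sqrt(sum((mu[[1]] - mu[[2]])^2))
  if (gap <= 10 * max(spread)) {
    stop("easy texture preset failed its separation guarantee (gap ",
         signif(gap, 4), " <= 10 * spread ", signif(max(spread), 4), ")")
  }
  invisible(TRUE)
}

#' Generate a tube (ridge) image
#'
#' A smoothed bright ridge of the given width through the image center at the
#' given orientation, plus optional noise; a stand-in for tubular neuronal
#' structures when testing Hessian features.  With zero noise, orientations
#' differing by 90 degrees give transposed images.
#'
#' @param size square image side.
#' @param width tube full width (must be below `size / 4`).
#' @param orientation angle in degrees (0 = along x).
#' @param noise_sigma Gaussian noise s.d., default 0.
#' @param seed RNG seed.
#' @return An [image_volume()] with `nz = 1`.
#' @export
gen_tube_image <- function(size = 64L, width = 4, orientation = 0,
                           noise_sigma = 0, seed = 1L) {
  if (width >= size / 4) stop("'width' must be below size / 4")
  withr::with_seed(seed, {
    th <- orientation * pi / 180
    ctr <- (size - 1) / 2
    xs <- matrix(seq_len(size) - 1 - ctr, size, size)
    ys <- matrix(seq_len(size) - 1 - ctr, size, size, byrow = TRUE)
    # distance to the center line with direction (cos th, sin th)
    dist_line <- abs(-sin(th) * xs + cos(th) * ys)
    img <- 200 * exp(-dist_line^2 / (2 * (width / 2)^2))
    if (noise_sigma > 0) {
      img <- img + matrix(abs(stats::rnorm(size^2, 0, noise_sigma)), size, size)
    }
    image_volume(img)
  })
}

#' Write a complete synthetic demo workspace
#'
#' Produces everything needed to exercise the full workflow without external
#' data: a training blob volume with positive (blob center) and negative
#' (background) ROI marker files, a test blob volume with ground-truth
#' centers, and an easy two-class texture tree.
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @return Invisibly, a list of the file paths written.
#' @export
gen_demo_workspace <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  train <- gen_blob_volume(blob_volume_spec(seed = seed))
  test <- gen_blob_volume(blob_volume_spec(seed = seed + 1L))
  train_tif <- file.path(dir, "train_volume.tif")
  test_tif <- file.path(dir, "test_volume.tif")
  write_image_volume(train$volume, train_tif)
  write_image_volume(test$volume, test_tif)
  write_vaa3d_marker(train$centers, file.path(dir, "pos.marker"))
  neg <- negative_coordinates(train$volume, train$centers,
                              n = nrow(train$centers) * 2L,
                              min_dist = 6, seed = seed + 2L)
  write_vaa3d_marker(neg, file.path(dir, "neg.marker"))
  write_vaa3d_marker(test$centers, file.path(dir, "test_truth.marker"))
  gen_texture_set(texture_set_spec(seed = seed + 3L),
                  file.path(dir, "textures"))
  invisible(list(
    train_volume = train_tif, test_volume = test_tif,
    pos_marker = file.path(dir, "pos.marker"),
    neg_marker = file.path(dir, "neg.marker"),
    test_truth = file.path(dir, "test_truth.marker"),
    textures = file.path(dir, "textures")
  ))
}

# background coordinates at least min_dist voxels from every center
negative_coordinates <- function(v, centers, n, min_dist = 6, seed = 1L) {
  d <- dim(v)
  withr::with_seed(seed, {
    out <- matrix(0L, 0, 3)
    tries <- 0L
    while (nrow(out) < n && tries < 20000L) {
      tries <- tries + 1L
      cand <- c(sample(0:(d[1] - 1L), 1L), sample(0:(d[2] - 1L), 1L),
                sample(0:(d[3] - 1L), 1L))
      dd <- sqrt((centers$x - cand[1])^2 + (centers$y - cand[2])^2 +
                   (centers$z - cand[3])^2)
      if (min(dd) >= min_dist) out <- rbind(out, cand)
    }
    coordinates(out[, 1], out[, 2], out[, 3])
  })
}
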