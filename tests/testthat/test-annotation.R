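# Local maxima, sliding-window annotation, center merging and multi-label
# annotation.

# trained ROI model over a blob volume, shared by several tests
train_blob_model <- function(seed = 1L, classifier = classifier_spec("svm-linear")) {
  td <- withr::local_tempdir(.local_envir = parent.frame())
  gen <- gen_blob_volume(blob_volume_spec(seed = seed))
  img <- file.path(td, "train.tif")
  write_image_volume(gen$volume, img)
  write_vaa3d_marker(gen$centers, file.path(td, "pos.marker"))
  neg <- imgchain:::negative_coordinates(gen$volume, gen$centers,
                                         n = 2L * nrow(gen$centers),
                                         min_dist = 6, seed = seed + 1L)
  write_vaa3d_marker(neg, file.path(td, "neg.marker"))
  rs <- load_roi_set(img, file.path(td, c("pos.marker", "neg.marker")),
                     patch_geometry(3, 3, 2))
  chain <- algorithm_chain(extractor_spec("aniso-wavelet-3d", levels = 2),
                           classifier, name = "aniso+clf")
  train_model(chain, rs)
}

test_that("local maxima match an exhaustive neighborhood-comparison oracle", {
  # single bright voxel
  vox <- array(0, c(8, 8, 4))
  vox[4, 5, 2] <- 100
  got <- local_maxima(image_volume(vox), radius = 1, floor = 10)
  expect_equal(got, coordinates(3, 4, 1), ignore_attr = TRUE)

  # constant volume below the floor: nothing
  flat <- image_volume(array(5, c(6, 6, 3)))
  expect_equal(nrow(local_maxima(flat, floor = 10)), 0L)

  # random smoothed volume vs. brute-force neighbor comparison
  withr::with_seed(100, {
    raw <- array(runif(14 * 12 * 6), c(14, 12, 6))
  })
  sm <- imgchain:::gaussian_derivative(raw, 1, c(0, 0, 0)) * 100
  v <- image_volume(sm)
  floor <- 30
  got <- local_maxima(v, radius = 1, floor = floor)
  d <- dim(sm)
  oracle <- list()
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    val <- sm[i, j, k]
    if (val <= floor) next
    is_max <- TRUE
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      ni <- i + di; nj <- j + dj; nk <- k + dk
      if ((di | dj | dk) && ni >= 1 && nj >= 1 && nk >= 1 &&
          ni <= d[1] && nj <= d[2] && nk <= d[3] &&
          sm[ni, nj, nk] > val) {
        is_max <- FALSE
      }
    }
    if (is_max) oracle[[length(oracle) + 1L]] <- c(i, j, k) - 1L
  }
  oracle <- do.call(rbind, oracle)
  # smoothed random fields have no plateaus, so the sets must match exactly
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(as.matrix(got), oracle, ignore_attr = TRUE)
})

test_that("plateaus contribute one representative, lexicographically smallest", {
  vox <- array(0, c(8, 8, 1))
  vox[3:4, 5:6, 1] <- 50 # a 2x2 constant plateau
  got <- local_maxima(image_volume(vox), radius = 1, floor = 10)
  expect_equal(got, coordinates(2, 4, 0), ignore_attr = TRUE)
})

test_that("the decision lattice honors the sliding interval", {
  model <- train_blob_model(seed = 110)
  # 2D lattice arithmetic checked on a 10x10 slice-like volume
  vox <- withr::with_seed(111, array(runif(10 * 10 * 5) * 50, c(10, 10, 5)))
  v <- image_volume(vox)
  g1 <- sliding_annotate(model, v, interval = 3)
  # sites 0,3,6,9 per x/y axis and 0,3 in z: 4*4*2
  expect_equal(nrow(g1), 32L)
  expect_setequal(unique(g1$x), c(0, 3, 6, 9))

  g2 <- sliding_annotate(model, v, interval = 5)
  expect_equal(nrow(g2), 2L * 2L * 1L)

  restrict <- coordinates(c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1), 2)
  g3 <- sliding_annotate(model, v, restrict_to = restrict)
  expect_equal(nrow(g3), 5L)
  expect_equal(g3[, c("x", "y", "z")], restrict, ignore_attr = TRUE)
})

test_that("interval-1 annotation equals all-lattice restriction", {
  model <- train_blob_model(seed = 112)
  vox <- withr::with_seed(113, array(runif(9 * 8 * 5) * 60, c(9, 8, 5)))
  v <- image_volume(vox)
  g_all <- sliding_annotate(model, v, interval = 1)
  lattice <- expand.grid(x = 0:8, y = 0:7, z = 0:4)
  g_restrict <- sliding_annotate(model, v,
                                 restrict_to = coordinates(lattice$x, lattice$y,
                                                           lattice$z))
  expect_equal(g_all$label, g_restrict$label)
  expect_equal(as.data.frame(g_all), as.data.frame(g_restrict))
  # determinism: a second run is identical
  expect_identical(as.data.frame(sliding_annotate(model, v, interval = 1)),
                   as.data.frame(g_all))
})

test_that("mean-shift merging counts blob modes correctly", {
  gen <- gen_blob_volume(blob_volume_spec(n_blobs = 2L, nx = 64, ny = 32,
                                          nz = 12, min_separation = 20,
                                          noise_sigma = 0, seed = 114))
  v <- gen$volume
  c1 <- gen$centers[1, ]; c2 <- gen$centers[2, ]

  # two candidates 1 voxel apart inside one blob merge to one center
  near <- coordinates(c(c1$x, c1$x + 1L), c(c1$y, c1$y), c(c1$z, c1$z))
  m1 <- merge_centers(near, v, merge_radius = 3)
  expect_equal(m1$count, 1L)

  # candidates at both blobs stay two objects
  both <- coordinates(c(c1$x, c2$x), c(c1$y, c2$y), c(c1$z, c2$z))
  m2 <- merge_centers(both, v, merge_radius = 3)
  expect_equal(m2$count, 2L)

  # a candidate offset by 2 voxels converges to within 1 voxel of the mode
  off <- coordinates(c1$x + 2L, c1$y, c1$z)
  m3 <- merge_centers(off, v, merge_radius = 3, shift_radius = 4)
  expect_equal(m3$count, 1L)
  expect_lte(sqrt(sum((unlist(m3$centers[1, ]) - unlist(c1))^2)), 1)

  # empty candidate list
  m0 <- merge_centers(coordinates(), v, merge_radius = 3)
  expect_equal(m0$count, 0L)
  expect_equal(nrow(m0$centers), 0L)
})

test_that("end-to-end counting recovers the truth on a fresh volume", {
  model <- train_blob_model(seed = 115)
  test_gen <- gen_blob_volume(blob_volume_spec(seed = 116))
  v <- test_gen$volume
  truth <- test_gen$centers

  maxima <- local_maxima(v, radius = 1)
  grid <- sliding_annotate(model, v, restrict_to = maxima)
  pos <- grid[grid$label == "pos", c("x", "y", "z")]
  merged <- merge_centers(pos, v, merge_radius = 4)

  expect_lte(abs(merged$count - nrow(truth)), ceiling(0.1 * nrow(truth)))

  # center matching F1 at 3-voxel tolerance
  dmat <- as.matrix(stats::dist(rbind(
    as.matrix(merged$centers), as.matrix(truth)
  )))[seq_len(nrow(merged$centers)), nrow(merged$centers) + seq_len(nrow(truth)),
      drop = FALSE]
  matched <- sum(apply(dmat, 2, min) <= 3)
  precision <- matched / nrow(merged$centers)
  recall <- matched / nrow(truth)
  f1 <- 2 * precision * recall / (precision + recall)
  expect_gte(f1, 0.9)
})

test_that("annotation outputs are written as CSV plus a label mask", {
  model <- train_blob_model(seed = 117)
  v <- gen_blob_volume(blob_volume_spec(seed = 118))$volume
  grid <- sliding_annotate(model, v, restrict_to = local_maxima(v))
  td <- withr::local_tempdir()
  write_annotation(grid, td, dim(v))
  decisions <- read.csv(file.path(td, "decisions.csv"))
  expect_equal(nrow(decisions), nrow(grid))
  mask <- read_image_volume(file.path(td, "mask.tif"))
  expect_equal(dim(mask), dim(v))
  classes <- readLines(file.path(td, "classes.txt"))
  pos_sites <- decisions[decisions$label == "pos", ]
  expect_true(all(mask$voxels[cbind(pos_sites$x + 1, pos_sites$y + 1,
                                    pos_sites$z + 1)] ==
                    match("pos", classes)))
})

test_that("multi-label annotation consolidates independent binary models", {
  td <- withr::local_tempdir()
  # two binary problems over the texture images: "low" present iff class_low,
  # "bright" present for a brightened copy of every 3rd image
  set <- gen_texture_set(texture_set_spec(per_class = 6L, seed = 119), td)
  labels <- lapply(seq_along(set$entries), function(i) {
    e <- set$entries[[i]]
    c(if (grepl("class_low", e$image)) "low" else "high",
      if (i %% 3 == 0) "extra" else NULL)
  })
  multiset <- set
  for (i in seq_along(labels)) multiset$entries[[i]]$labels <- labels[[i]]
  multiset$classes <- c("extra", "high", "low")

  chain <- algorithm_chain(extractor_spec("haar2d"), classifier_spec("knn"))
  m_low <- train_model(chain, binary_label_set(multiset, "low"))
  m_high <- train_model(chain, binary_label_set(multiset, "high"))
  models <- list(low = m_low, high = m_high)

  rep <- multilabel_annotate(models, multiset)
  expect_equal(nrow(rep), length(multiset$entries))
  presence <- attr(rep, "presence")
  # output equals the union of independent binary predictions
  solo_low <- predict_images(m_low, multiset)$label == "low"
  solo_high <- predict_images(m_high, multiset)$label == "high"
  expect_equal(unname(presence[, "low"]), solo_low)
  expect_equal(unname(presence[, "high"]), solo_high)
  # the separable problem is annotated perfectly: exactly one of low/high each
  expect_true(all(rowSums(presence) == 1))

  # non-binary models are rejected
  expect_error(multilabel_annotate(list(low = m_low, bogus = m_low), multiset),
               class = "imgchain_contract_error")
})
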