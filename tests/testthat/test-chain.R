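# Chain engine: feature aggregation, repeated stratified CV, chain
# comparison, and model persistence.

make_texture_set <- function(seed = 1L, per_class = 10L) {
  td <- withr::local_tempdir(.local_envir = parent.frame())
  gen_texture_set(texture_set_spec(per_class = per_class, seed = seed), td)
}

test_that("aggregated features are the concatenation of extractor outputs", {
  set <- make_texture_set(seed = 80)
  fs <- featurize_set(list(
    extractor_spec("haar2d", levels = 2),        # 14 values
    extractor_spec("hu-2d")                      # 8 values
  ), set)
  expect_equal(ncol(fs$features), 22L)
  expect_equal(nrow(fs$features), 20L)
  # single-extractor matrix equals that extractor applied per sample
  fs1 <- featurize_set(extractor_spec("hu-2d"), set)
  v <- read_image_volume(set$entries[[4]]$image)
  expect_equal(fs1$features[4, ], hu_moments_2d(v))
  # aggregation preserves extractor order in the columns
  expect_equal(unname(fs$features[4, 15:22]), unname(fs1$features[4, ]))
})

test_that("permuting sample order permutes feature rows identically", {
  set <- make_texture_set(seed = 81, per_class = 4L)
  fs <- featurize_set(extractor_spec("haar2d"), set)
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  permuted <- set
  permuted$entries <- set$entries[perm]
  fs2 <- featurize_set(extractor_spec("haar2d"), permuted)
  expect_equal(fs2$features, fs$features[perm, ])
  expect_equal(fs2$labels, fs$labels[perm])
})

test_that("the default protocol yields 25 runs with recomputable summaries", {
  set <- make_texture_set(seed = 82)
  chain <- algorithm_chain(extractor_spec("haar2d"), classifier_spec("knn"))
  res <- evaluate_chain(chain, set, eval_protocol(seed = 3))
  expect_length(res$per_run, 25L)
  expect_true(all(res$per_run >= 0 & res$per_run <= 1))
  expect_equal(res$mean, mean(res$per_run), tolerance = 1e-12)
  expect_equal(res$variance, mean((res$per_run - mean(res$per_run))^2),
               tolerance = 1e-12)
})

test_that("the easy texture set is perfectly classified by Haar-stats + 3NN", {
  set <- make_texture_set(seed = 83)
  chain <- algorithm_chain(extractor_spec("haar2d", levels = 2),
                           classifier_spec("knn", k = 3))
  res <- evaluate_chain(chain, set, eval_protocol(seed = 1))
  expect_equal(res$mean, 1.0)
  expect_equal(res$variance, 0.0)
})

test_that("label shuffling drives accuracy to chance", {
  set <- make_texture_set(seed = 84)
  shuffled <- set
  withr::with_seed(85, {
    labs <- sample(vapply(set$entries, function(e) e$labels, "")) # balanced
  })
  for (i in seq_along(shuffled$entries)) shuffled$entries[[i]]$labels <- labs[i]
  chain <- algorithm_chain(extractor_spec("haar2d"), classifier_spec("knn"))
  res <- evaluate_chain(chain, shuffled, eval_protocol(seed = 2))
  # 100 held-out decisions around chance 0.5
  expect_gte(res$mean, 0.35)
  expect_lte(res$mean, 0.65)
})

test_that("comparison ranks informative chains above constant ones", {
  set <- make_texture_set(seed = 86)
  if (!"const-feature" %in% list_plugins()$extractor) {
    register_plugin("extractor", "const-feature",
                    function(p) function(v) c(const = 1))
  }
  informative <- algorithm_chain(extractor_spec("haar2d"),
                                 classifier_spec("knn"), name = "haar+3nn")
  constant <- algorithm_chain(extractor_spec("const-feature"),
                              classifier_spec("knn"), name = "constant")
  cmp <- compare_chains(list(constant, informative), set,
                        eval_protocol(seed = 4))
  expect_equal(cmp$results[[1]]$name, "haar+3nn")
  expect_equal(cmp$winner$name, "haar+3nn")
  expect_equal(cmp$results[[1]]$mean, 1.0)
  expect_lt(cmp$results[[2]]$mean, 0.7)

  # single chain: that chain wins
  solo <- compare_chains(list(informative), set, eval_protocol(seed = 4))
  expect_equal(solo$winner$name, "haar+3nn")
})

test_that("comparisons are deterministic and fold-paired across chains", {
  set <- make_texture_set(seed = 87)
  c1 <- algorithm_chain(extractor_spec("haar2d"), classifier_spec("knn"),
                        name = "a")
  c2 <- algorithm_chain(extractor_spec("hu-2d"), classifier_spec("knn"),
                        name = "b")
  p <- eval_protocol(seed = 11)
  cmp1 <- compare_chains(list(c1, c2), set, p)
  cmp2 <- compare_chains(list(c1, c2), set, p)
  expect_identical(lapply(cmp1$results, `[[`, "per_run"),
                   lapply(cmp2$results, `[[`, "per_run"))
  expect_identical(vapply(cmp1$results, `[[`, "", "name"),
                   vapply(cmp2$results, `[[`, "", "name"))
  # identical fold membership hashes for every chain
  by_name <- function(cmp, nm) {
    cmp$results[[which(vapply(cmp$results, `[[`, "", "name") == nm)]]
  }
  expect_identical(by_name(cmp1, "a")$fold_hashes, by_name(cmp1, "b")$fold_hashes)
})

test_that("held-out rows never leak into selector or classifier fitting", {
  withr::with_seed(88, {
    n <- 60
    y <- rep(c("a", "b"), each = n / 2)
    x <- matrix(rnorm(n * 6), n, 6)
    colnames(x) <- sprintf("f%d", 1:6)
  })
  protocol <- eval_protocol(folds = 5, repeats = 1, seed = 9)
  folds <- imgchain:::make_folds(y, protocol)
  chain <- algorithm_chain(extractor_spec("haar2d"),
                           classifier_spec("knn"),
                           selectors = list(selector_spec("fisher", 1)))
  # poison a column with the label in exactly one fold's held-out rows (train
  # rows keep pure noise), then look at that fold's accuracy: if fitting ever
  # saw the held-out rows, the poisoned column would be selected and that
  # fold would be classified perfectly
  poisoned_acc <- vapply(sort(unique(folds[[1]])), function(f) {
    leak <- x
    test_rows <- folds[[1]] == f
    leak[test_rows, 6] <- ifelse(y[test_rows] == "a", -100, 100)
    res <- imgchain:::cv_evaluate(leak, y, chain, protocol, fold_assign = folds)
    res$per_run[f]
  }, 1)
  expect_lt(mean(poisoned_acc), 0.75) # stays near chance
})

test_that("models survive a save/load round trip bit-identically", {
  set <- make_texture_set(seed = 89)
  chain <- algorithm_chain(extractor_spec("haar2d"),
                           classifier_spec("svm-linear"),
                           selectors = list(selector_spec("fisher", 10)))
  model <- train_model(chain, set)
  td <- withr::local_tempdir()
  path <- file.path(td, "model.rds")
  save_model(model, path)
  reloaded <- load_model(path)

  probes <- gen_texture_set(texture_set_spec(per_class = 25L, seed = 90),
                            file.path(td, "probes"))
  expect_identical(predict_images(model, probes),
                   predict_images(reloaded, probes))

  # truncated archives fail with a format error, not a crash
  bytes <- readBin(path, "raw", file.size(path))
  trunc_path <- file.path(td, "trunc.rds")
  writeBin(bytes[1:40], trunc_path)
  expect_error(load_model(trunc_path), class = "imgchain_data_error")
  # arbitrary rds content is refused
  other <- file.path(td, "other.rds")
  saveRDS(list(a = 1), other)
  expect_error(load_model(other), class = "imgchain_data_error")
  # version bumps are named
  bad <- unclass(model); class(bad) <- "trained_model"
  bad$format_version <- 99L
  saveRDS(bad, other)
  expect_error(load_model(other), "version", class = "imgchain_data_error")
})

test_that("folds clamp with a warning when a class is too small", {
  set <- make_texture_set(seed = 91, per_class = 3L)
  chain <- algorithm_chain(extractor_spec("haar2d"), classifier_spec("knn"))
  expect_warning(
    res <- evaluate_chain(chain, set, eval_protocol(folds = 5, repeats = 2)),
    "clamped"
  )
  expect_length(res$per_run, 3L * 2L)
})
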