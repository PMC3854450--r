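# Chain evaluation by repeated stratified cross-validation, chain
# comparison, and model persistence.
#
# The default protocol is five-fold cross-validation repeated five times
# with reshuffling, i.e. 25 train/test runs per chain; the mean and the
# population variance of the 25 recognition rates are reported.  Fold
# assignments are derived deterministically from the protocol seed and the
# labels only, so every chain under comparison sees identical partitions
# (paired comparison).

#' Evaluation protocol
#'
#' @param folds cross-validation folds, default 5 (clamped with a warning if
#'   a class has fewer members).
#' @param repeats shuffle-and-split repetitions, default 5; total runs =
#'   `folds * repeats`.
#' @param seed integer seed for the fold shuffling.
#' @param stratified keep class proportions per fold (default `TRUE`).
#' @return An object of class `eval_protocol`.
#' @export
eval_protocol <- function(folds = 5L, repeats = 5L, seed = 1L, stratified = TRUE) {
  if (!is_count(folds, 2L)) stop("'folds' must be an integer >= 2")
  if (!is_count(repeats)) stop("'repeats' must be a positive integer")
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed), stratified = isTRUE(stratified)),
            class = "eval_protocol")
}

# Fold assignments: list with one integer vector (fold id per sample) per
# repeat.  Depends only on (labels, protocol), never on features, so all
# chains are evaluated on identical partitions.
make_folds <- function(labels, protocol) {
  folds <- protocol$folds
  min_class <- min(table(labels))
  if (min_class < folds) {
    warning(sprintf("smallest class has %d members; folds clamped from %d to %d",
                    min_class, folds, max(2L, min_class)))
    folds <- max(2L, as.integer(min_class))
  }
  lapply(seq_len(protocol$repeats), function(r) {
    withr::with_seed(protocol$seed + 7919L * r, {
      assign <- integer(length(labels))
      if (protocol$stratified) {
        for (cls in unique(labels)) {
          idx <- sample(which(labels == cls))
          assign[idx] <- rep_len(seq_len(folds), length(idx))
        }
      } else {
        assign[sample(seq_along(labels))] <- rep_len(seq_len(folds), length(labels))
      }
      assign
    })
  })
}

fold_hash <- function(assign) paste(assign, collapse = ".")

# One full CV pass of a chain over a precomputed feature set.  Selectors and
# the classifier are fitted on training rows only.
cv_evaluate <- function(x, labels, chain, protocol, fold_assign = NULL) {
  fold_assign <- fold_assign %||% make_folds(labels, protocol)
  per_run <- numeric(0)
  hashes <- character(0)
  n_selected <- ncol(x)
  for (r in seq_along(fold_assign)) {
    assign <- fold_assign[[r]]
    for (f in sort(unique(assign))) {
      test <- assign == f
      xt <- x[!test, , drop = FALSE]
      yt <- labels[!test]
      kept <- seq_len(ncol(x))
      if (length(chain$selectors) > 0L) {
        sel <- cascade_select(xt, yt, chain$selectors)
        xt <- sel$x
        kept <- sel$kept
      }
      n_selected <- length(kept)
      model <- fit_classifier(chain$classifier, xt, yt)
      pred <- predict(model, x[test, kept, drop = FALSE])
      per_run <- c(per_run, mean(pred == labels[test]))
      hashes <- c(hashes, sprintf("r%d.f%d:%s", r, f, fold_hash(assign)))
    }
  }
  list(per_run = per_run, fold_hashes = hashes, n_selected = n_selected)
}

#' Evaluate one algorithm chain
#'
#' Features are aggregated once per sample set; then, for each repeat, the
#' samples are reshuffled (seed derived from the protocol seed) and split
#' into stratified folds.  Per fold, the selector cascade and the classifier
#' are fitted on the training rows only and the recognition rate is scored on
#' the held-out rows.
#'
#' @param chain an [algorithm_chain()].
#' @param samples a `labeled_image_set` or `roi_set` with >= 2 classes.
#' @param protocol an [eval_protocol()].
#' @param channel channel selector for image reading.
#' @return An object of class `chain_result`: per-run accuracies, their mean
#'   and population variance, feature counts before and after selection, and
#'   the fold-membership hashes.
#' @export
evaluate_chain <- function(chain, samples, protocol = eval_protocol(),
                           channel = "all") {
  fs <- featurize_set(chain, samples, channel)
  if (length(unique(fs$labels)) < 2L) {
    stop("chain evaluation requires at least 2 classes")
  }
  cv <- cv_evaluate(fs$features, fs$labels, chain, protocol)
  structure(
    list(
      chain = chain, name = chain$name,
      per_run = cv$per_run,
      mean = mean(cv$per_run),
      variance = pop_var(cv$per_run),
      n_features = ncol(fs$features),
      n_selected = cv$n_selected,
      fold_hashes = cv$fold_hashes,
      protocol = protocol
    ),
    class = "chain_result"
  )
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf("<chain_result> %s\n  %d runs: mean accuracy %.4f, variance %.6f, features %d -> %d\n",
              x$name, length(x$per_run), x$mean, x$variance,
              x$n_features, x$n_selected))
  invisible(x)
}

#' Compare algorithm chains and pick a winner
#'
#' All chains are evaluated under identical fold assignments (same derived
#' seeds), so the comparison is paired.  Results are ordered by mean accuracy
#' (descending); ties are broken by fewer selected features (preferring
#' compact models), then by chain order.  The winner is the best among the
#' compared chains -- not necessarily a global optimum.
#'
#' @param chains list of [algorithm_chain()]s (at least one).
#' @param samples a `labeled_image_set` or `roi_set`.
#' @param protocol an [eval_protocol()].
#' @param channel channel selector for image reading.
#' @return An object of class `chain_comparison`: ordered `results` plus
#'   `winner` (the top chain).
#' @export
compare_chains <- function(chains, samples, protocol = eval_protocol(),
                           channel = "all") {
  if (inherits(chains, "algorithm_chain")) chains <- list(chains)
  if (length(chains) == 0L) stop("at least one chain is required")
  results <- lapply(chains, evaluate_chain, samples = samples,
                    protocol = protocol, channel = channel)
  ord <- order(
    -vapply(results, `[[`, 1, "mean"),
    vapply(results, `[[`, 1L, "n_selected"),
    seq_along(results)
  )
  structure(list(results = results[ord], winner = results[[ord[1]]]$chain,
                 protocol = protocol),
            class = "chain_comparison")
}

#' @export
print.chain_comparison <- function(x, ...) {
  cat("<chain_comparison>\n")
  for (i in seq_along(x$results)) {
    r <- x$results[[i]]
    cat(sprintf("  %d. %-45s mean %.4f var %.6f (%d -> %d features)\n",
                i, r$name, r$mean, r$variance, r$n_features, r$n_selected))
  }
  cat("winner:", x$winner$name, "\n")
  invisible(x)
}

#' Comparison summary as a data frame
#'
#' @param comparison a `chain_comparison`.
#' @return A data frame with one row per chain.
#' @export
comparison_summary <- function(comparison) {
  data.frame(
    rank = seq_along(comparison$results),
    chain = vapply(comparison$results, `[[`, "", "name"),
    mean_accuracy = vapply(comparison$results, `[[`, 1, "mean"),
    variance = vapply(comparison$results, `[[`, 1, "variance"),
    n_features = vapply(comparison$results, `[[`, 1L, "n_features"),
    n_selected = vapply(comparison$results, `[[`, 1L, "n_selected"),
    runs = vapply(comparison$results, function(r) length(r$per_run), 1L)
  )
}

#' Write a machine-readable comparison report
#'
#' Writes `comparison.json` (per chain: name, per-run accuracies, mean,
#' variance, feature counts; plus the winner) and `comparison.csv` (the
#' summary table) into `dir`.
#'
#' @param comparison a `chain_comparison`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_comparison_report <- function(comparison, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    winner = comparison$winner$name,
    protocol = unclass(comparison$protocol),
    chains = lapply(comparison$results, function(r) {
      list(name = r$name, per_run = r$per_run, mean = r$mean,
           variance = r$variance, n_features = r$n_features,
           n_selected = r$n_selected)
    })
  )
  jsonlite::write_json(payload, file.path(dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(comparison_summary(comparison),
                   file.path(dir, "comparison.csv"), row.names = FALSE)
  invisible(dir)
}

# ---- model training and persistence -----------------------------------------

MODEL_FORMAT_VERSION <- 1L

#' Train a model from a chain
#'
#' Fits the selector cascade and the classifier on the full labeled set.  The
#' model records the kept feature columns, the class list, the channel and
#' (in ROI mode) the patch geometry used in training.
#'
#' @param chain an [algorithm_chain()].
#' @param samples a `labeled_image_set` or `roi_set`.
#' @param channel channel selector for image reading.
#' @return An object of class `trained_model`.
#' @export
train_model <- function(chain, samples, channel = "all") {
  fs <- featurize_set(chain, samples, channel)
  x <- fs$features
  kept <- seq_len(ncol(x))
  if (length(chain$selectors) > 0L) {
    sel <- cascade_select(x, fs$labels, chain$selectors)
    x <- sel$x
    kept <- sel$kept
  }
  clf <- fit_classifier(chain$classifier, x, fs$labels)
  structure(
    list(
      format_version = MODEL_FORMAT_VERSION,
      chain = chain,
      kept = kept,
      feature_names = colnames(fs$features),
      classifier = clf,
      classes = sort(unique(fs$labels)),
      channel = channel,
      geometry = if (inherits(samples, "roi_set")) samples$geometry else NULL
    ),
    class = "trained_model"
  )
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s; classes: %s; %d/%d features%s\n",
              x$chain$name, paste(x$classes, collapse = ", "),
              length(x$kept), length(x$feature_names),
              if (!is.null(x$geometry)) {
                sprintf("; patch %dx%dx%d", 2 * x$geometry$rx + 1,
                        2 * x$geometry$ry + 1, 2 * x$geometry$rz + 1)
              } else ""))
  invisible(x)
}

# features -> selected columns, with provenance check
model_select_features <- function(model, features) {
  if (!identical(colnames(features), model$feature_names)) {
    stop_contract("feature provenance does not match the trained model")
  }
  features[, model$kept, drop = FALSE]
}

#' Predict labels for whole images with a trained model
#'
#' @param model a `trained_model` trained on whole-image samples.
#' @param images character vector of image paths, or a `labeled_image_set`.
#' @return A data frame with columns `image` and `label`.
#' @export
predict_images <- function(model, images) {
  set <- if (inherits(images, "labeled_image_set")) images else {
    new_labeled_image_set(
      lapply(images, function(p) list(image = p, labels = "unknown")),
      classes = "unknown", mode = "target-file"
    )
  }
  fs <- featurize_set(model$chain, set, model$channel)
  x <- model_select_features(model, fs$features)
  data.frame(image = fs$ids, label = predict(model$classifier, x),
             stringsAsFactors = FALSE)
}

#' Save / load a trained model
#'
#' The model is written as a single versioned archive file; a reloaded model
#' produces bit-identical predictions.  Loading a file that is not a model
#' archive, or one with a different format version, raises a data error
#' rather than crashing.
#'
#' @param model a `trained_model`.
#' @param path archive path (conventionally `.rds`).
#' @return `save_model`: `path`, invisibly.  `load_model`: the model.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "trained_model")) stop("'model' must be a trained_model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_data("model archive not found: ", path)
  model <- tryCatch(readRDS(path), error = function(e) {
    stop_data("not a readable model archive: ", path)
  })
  if (!inherits(model, "trained_model") || is.null(model$format_version)) {
    stop_data("file is not a trained model archive: ", path)
  }
  if (model$format_version != MODEL_FORMAT_VERSION) {
    stop_data(sprintf("model format version %s is not supported (expected %d)",
                      model$format_version, MODEL_FORMAT_VERSION))
  }
  model
}
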