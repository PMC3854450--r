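# Algorithm chains and feature aggregation.
#
# A chain is an ordered list of feature extractors, an optional cascade of
# feature selectors and exactly one classifier; it is the unit of model
# selection.  When several extractors are used their features are linearly
# aggregated: the combined dimensionality is the sum of the individual
# vector lengths.

#' Extractor specification
#'
#' @param name a registered extractor name (see [list_plugins()]).
#' @param ... extractor parameters (e.g. `levels`, `pooling`, `scales`,
#'   `count`, `threshold`, `sigma`).
#' @return An object of class `extractor_spec`.
#' @export
extractor_spec <- function(name, ...) {
  structure(list(name = name, params = list(...)), class = "extractor_spec")
}

#' Algorithm chain
#'
#' @param extractors non-empty list of [extractor_spec()]s.
#' @param classifier a [classifier_spec()].
#' @param selectors possibly empty list of [selector_spec()]s, applied as a
#'   cascade.
#' @param name chain name used in reports; chains with the same algorithms
#'   but different parameters are distinct chains.
#' @return An object of class `algorithm_chain`.
#' @export
algorithm_chain <- function(extractors, classifier, selectors = list(),
                            name = NULL) {
  if (inherits(extractors, "extractor_spec")) extractors <- list(extractors)
  if (inherits(selectors, "selector_spec")) selectors <- list(selectors)
  if (length(extractors) == 0L) stop("a chain needs at least one extractor")
  if (!inherits(classifier, "classifier_spec")) {
    stop("'classifier' must be a classifier_spec")
  }
  name <- name %||% paste(
    c(vapply(extractors, `[[`, "", "name"),
      if (length(selectors)) sprintf("%s(%d)",
        vapply(selectors, `[[`, "", "criterion"),
        vapply(selectors, `[[`, 1L, "n_keep")),
      classifier$kind),
    collapse = " + "
  )
  structure(list(extractors = extractors, selectors = selectors,
                 classifier = classifier, name = name),
            class = "algorithm_chain")
}

#' @export
print.algorithm_chain <- function(x, ...) {
  cat("<algorithm_chain>", x$name, "\n")
  invisible(x)
}

sample_volumes <- function(samples, channel = "all") {
  # Iterator-style accessors so at most one image is resident per pass.
  if (inherits(samples, "labeled_image_set")) {
    list(
      n = length(samples$entries),
      labels = vapply(samples$entries, function(e) e$labels[1], ""),
      ids = vapply(samples$entries, function(e) basename(e$image), ""),
      get = function(i) read_image_volume(samples$entries[[i]]$image, channel)
    )
  } else if (inherits(samples, "roi_set")) {
    vol <- read_image_volume(samples$image, channel)
    geom <- samples$geometry
    list(
      n = nrow(samples$points),
      labels = samples$points$label,
      ids = sprintf("%s@%d,%d,%d", basename(samples$image),
                    samples$points$x, samples$points$y, samples$points$z),
      get = function(i) extract_patch(vol, samples$points[i, ], geom)
    )
  } else {
    stop("'samples' must be a labeled_image_set or roi_set")
  }
}

#' Aggregate chain features over a sample set
#'
#' Visits samples sequentially (one image resident at a time), applies every
#' extractor and concatenates the vectors in extractor order.  Column names
#' carry the provenance (extractor name and per-index tag).  An extractor
#' whose output length varies across samples violates its contract and the
#' offending sample and extractor are named in the error.
#'
#' @param extractors list of [extractor_spec()]s (or an [algorithm_chain()],
#'   whose extractors are used).
#' @param samples a `labeled_image_set` or `roi_set`.
#' @param channel channel selector passed to [read_image_volume()].
#' @return A list of class `feature_set` with `features` (numeric matrix,
#'   one row per sample), `labels` and `ids`.
#' @export
featurize_set <- function(extractors, samples, channel = "all") {
  if (inherits(extractors, "algorithm_chain")) extractors <- extractors$extractors
  if (inherits(extractors, "extractor_spec")) extractors <- list(extractors)
  src <- sample_volumes(samples, channel)
  if (src$n == 0L) stop("empty sample set")
  fns <- lapply(extractors, resolve_extractor)
  names(fns) <- vapply(extractors, `[[`, "", "name")
  rows <- vector("list", src$n)
  for (i in seq_len(src$n)) {
    vol <- src$get(i)
    vec <- lapply(seq_along(fns), function(j) {
      out <- tryCatch(fns[[j]](vol), error = function(e) {
        stop_data("extractor '", names(fns)[j], "' failed on sample '",
                  src$ids[i], "': ", conditionMessage(e))
      })
      if (is.null(names(out))) {
        names(out) <- sprintf("%s.%d", names(fns)[j], seq_along(out))
      }
      out
    })
    rows[[i]] <- unlist(vec)
    if (i > 1L && length(rows[[i]]) != length(rows[[1]])) {
      lens_now <- vapply(vec, length, 1L)
      stop_contract(
        "extractor output length changed at sample '", src$ids[i],
        "' (lengths ", paste(names(fns), lens_now, sep = "=", collapse = ", "),
        "); extractor outputs must have fixed length"
      )
    }
  }
  features <- do.call(rbind, rows)
  rownames(features) <- src$ids
  structure(list(features = features, labels = src$labels, ids = src$ids),
            class = "feature_set")
}
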