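# Fisher-criterion feature scoring and filter-style selection.
#
# Selector fitting always happens inside each training fold during
# cross-validation (see evaluate_chain), never on the full set, so held-out
# rows can never leak into the selection.

#' Fisher scores of feature columns
#'
#' Multiclass Fisher criterion per column `j`:
#' `score_j = sum_c p_c (mu_cj - mu_j)^2 / (sum_c p_c s2_cj + eps)`
#' with class proportions `p_c`, class means `mu_cj`, grand mean `mu_j` and
#' (population) class variances `s2_cj`; `eps = 1e-12` regularizes the
#' denominator so zero-within-variance columns rank on top without dividing
#' by zero.  Scores are non-negative; a column constant across all samples
#' scores 0.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param labels per-row class labels (at least 2 classes, 2 samples each).
#' @param eps denominator regularizer, default `1e-12`.
#' @return Numeric vector of one score per column.
#' @export
fisher_scores <- function(x, labels, eps = 1e-12) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) stop("one label per row is required")
  classes <- unique(labels)
  if (length(classes) < 2L) stop("Fisher scores require at least 2 classes")
  if (any(table(labels) < 2L)) stop("each class needs at least 2 samples")
  p <- as.numeric(table(labels)[classes]) / nrow(x)
  grand <- colMeans(x)
  between <- numeric(ncol(x))
  within <- numeric(ncol(x))
  for (i in seq_along(classes)) {
    xc <- x[labels == classes[i], , drop = FALSE]
    mu_c <- colMeans(xc)
    s2_c <- colMeans(xc^2) - mu_c^2 # population variance per column
    between <- between + p[i] * (mu_c - grand)^2
    within <- within + p[i] * s2_c
  }
  between / (within + eps)
}

#' Keep the highest-scoring feature columns
#'
#' Keeps the `n_keep` columns with the largest scores; kept columns retain
#' their original relative order and ties are broken toward the lower
#' original index.  `n_keep >= ncol(x)` is the identity.
#'
#' @param x numeric feature matrix.
#' @param scores one score per column (see [fisher_scores()]).
#' @param n_keep number of columns to keep.
#' @return A list with `x` (the reduced matrix) and `kept` (original column
#'   indices, ascending).
#' @export
select_features <- function(x, scores, n_keep) {
  x <- as.matrix(x)
  if (length(scores) != ncol(x)) stop("one score per column is required")
  if (!is_count(n_keep)) stop("'n_keep' must be a positive integer")
  n_keep <- min(as.integer(n_keep), ncol(x))
  kept <- sort(order(-scores, seq_along(scores))[seq_len(n_keep)])
  list(x = x[, kept, drop = FALSE], kept = kept)
}

#' Selector specification
#'
#' @param criterion scoring criterion; `"fisher"` is built in, other names
#'   resolve through the plugin registry.
#' @param n_keep number of features the selector keeps.
#' @return An object of class `selector_spec`.
#' @export
selector_spec <- function(criterion = "fisher", n_keep) {
  if (!is_count(n_keep)) stop("'n_keep' must be a positive integer")
  structure(list(criterion = criterion, n_keep = as.integer(n_keep)),
            class = "selector_spec")
}

resolve_selector <- function(criterion) {
  if (identical(criterion, "fisher")) return(fisher_scores)
  reg <- registry_get("selector", criterion)
  if (is.null(reg)) {
    stop_config("unknown selector criterion '", criterion, "'")
  }
  reg
}

#' Cascaded feature selection
#'
#' Applies selectors sequentially: each stage re-scores the columns surviving
#' the previous stage and keeps its own `n_keep` best.  A stage asking for
#' more columns than survive is clamped with a warning.  The returned index
#' mapping composes back to the original columns.
#'
#' @param x numeric feature matrix.
#' @param labels per-row class labels.
#' @param selectors list of [selector_spec()]s (non-empty).
#' @return A list with `x` (reduced matrix) and `kept` (original column
#'   indices, ascending).
#' @export
cascade_select <- function(x, labels, selectors) {
  if (length(selectors) == 0L) stop("'selectors' must be non-empty")
  x <- as.matrix(x)
  kept <- seq_len(ncol(x))
  for (sel in selectors) {
    n_keep <- sel$n_keep
    if (n_keep > ncol(x)) {
      warning(sprintf("selector n_keep = %d exceeds %d surviving columns; clamped",
                      n_keep, ncol(x)))
      n_keep <- ncol(x)
    }
    score_fn <- resolve_selector(sel$criterion)
    stage <- select_features(x, score_fn(x, labels), n_keep)
    x <- stage$x
    kept <- kept[stage$kept]
  }
  list(x = x, kept = kept)
}
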