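# Uniform train/predict contract over the classifier inventory.
#
# Built-in kinds wrap established implementations (e1071::svm and
# naiveBayes, rpart, randomForest); kNN is implemented here because the
# package's tie-break contract (label of the single nearest neighbor among
# tied classes) is part of the interface.  Defaults follow the tool's
# conventions: 3NN; linear-kernel SVM with regularization parameter 1.

CLASSIFIER_KINDS <- c("knn", "svm-linear", "naive-bayes", "decision-tree",
                      "random-forest")

#' Classifier specification
#'
#' @param kind one of `"knn"`, `"svm-linear"`, `"naive-bayes"`,
#'   `"decision-tree"`, `"random-forest"`, or a plugin classifier name.
#' @param k kNN neighbor count, default 3.
#' @param cost SVM regularization parameter C, default 1.
#' @param ntree random-forest tree count, default 100.
#' @param maxdepth optional decision-tree depth cap.
#' @param scale if `TRUE`, features are z-scaled per column (using training
#'   statistics) before fitting and prediction.  Default `FALSE`.
#' @param seed integer seed making stochastic kinds reproducible.
#' @param params free-form parameter list for plugin classifiers.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind, k = 3L, cost = 1, ntree = 100L,
                            maxdepth = NULL, scale = FALSE, seed = 1L,
                            params = list()) {
  structure(
    list(kind = kind, k = as.integer(k), cost = cost, ntree = as.integer(ntree),
         maxdepth = maxdepth, scale = isTRUE(scale), seed = as.integer(seed),
         params = params),
    class = "classifier_spec"
  )
}

feature_frame <- function(x) {
  df <- as.data.frame(x)
  names(df) <- sprintf("f%d", seq_len(ncol(df)))
  df
}

#' Fit a classifier
#'
#' Deterministic given `(spec$seed, x, labels)`; stochastic kinds
#' (random forest) are fully reproducible under the seed.
#'
#' @param spec a [classifier_spec()].
#' @param x numeric feature matrix (rows = samples); column names are the
#'   feature provenance tags and must match at prediction time.
#' @param labels per-row class labels (at least 2 classes; at least as many
#'   rows as classes).
#' @return An object of class `trained_classifier`.
#' @export
fit_classifier <- function(spec, x, labels) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("training requires at least 2 classes")
  if (nrow(x) < length(classes)) stop("fewer training rows than classes")
  scaling <- NULL
  if (spec$scale) {
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    sdv[sdv == 0] <- 1
    scaling <- list(mu = mu, sd = sdv)
    x <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  }
  y <- factor(labels, levels = classes)
  fit <- withr::with_seed(spec$seed, switch(spec$kind,
    "knn" = list(x = x, y = y),
    "svm-linear" = e1071::svm(x = x, y = y, kernel = "linear",
                              cost = spec$cost, scale = FALSE),
    "naive-bayes" = e1071::naiveBayes(feature_frame(x), y),
    "decision-tree" = {
      df <- feature_frame(x)
      df$.label <- y
      ctl <- rpart::rpart.control(minsplit = 2L, minbucket = 1L, cp = 0,
        maxdepth = spec$maxdepth %||% 30L, xval = 0L)
      rpart::rpart(.label ~ ., data = df, method = "class", control = ctl)
    },
    "random-forest" = randomForest::randomForest(x = x, y = y, ntree = spec$ntree),
    {
      plugin <- registry_get("classifier", spec$kind)
      if (is.null(plugin)) {
        stop_config("unknown classifier kind '", spec$kind, "'; built-in kinds are: ",
                    paste(CLASSIFIER_KINDS, collapse = ", "))
      }
      plugin$fit(x, y, spec$params)
    }
  ))
  structure(
    list(spec = spec, fit = fit, classes = classes, features = colnames(x),
         scaling = scaling),
    class = "trained_classifier"
  )
}

knn_predict <- function(fit, k, newdata) {
  train <- fit$x
  # squared Euclidean distances probe x train
  d2 <- outer(rowSums(newdata^2), rowSums(train^2), "+") -
    2 * newdata %*% t(train)
  k <- min(k, nrow(train))
  apply(d2, 1, function(dr) {
    ord <- order(dr, seq_along(dr)) # deterministic among exact ties
    nb <- fit$y[ord[seq_len(k)]]
    votes <- table(nb)
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) return(top)
    # tie: label of the single nearest neighbor among the tied classes
    as.character(nb[match(TRUE, as.character(nb) %in% top)])
  })
}

#' Predict with a trained classifier
#'
#' Emits one label per row.  Probe columns must match the training feature
#' provenance exactly.
#'
#' @param object a `trained_classifier`.
#' @param newdata numeric feature matrix with the training columns.
#' @param ... unused.
#' @return Character vector of predicted labels (always from the training
#'   class list).
#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) colnames(newdata) <- sprintf("V%d", seq_len(ncol(newdata)))
  if (!identical(colnames(newdata), object$features)) {
    diff <- c(setdiff(object$features, colnames(newdata)),
              setdiff(colnames(newdata), object$features))
    stop_contract("probe features do not match the trained model; differing tags: ",
                  paste(unique(diff), collapse = ", "))
  }
  if (!is.null(object$scaling)) {
    newdata <- sweep(sweep(newdata, 2, object$scaling$mu), 2, object$scaling$sd, "/")
  }
  spec <- object$spec
  out <- switch(spec$kind,
    "knn" = knn_predict(object$fit, spec$k, newdata),
    "svm-linear" = as.character(stats::predict(object$fit, newdata)),
    "naive-bayes" = as.character(stats::predict(object$fit, feature_frame(newdata))),
    "decision-tree" = as.character(stats::predict(object$fit,
      feature_frame(newdata), type = "class")),
    "random-forest" = as.character(stats::predict(object$fit, newdata)),
    {
      plugin <- registry_get("classifier", spec$kind)
      as.character(plugin$predict(object$fit, newdata))
    }
  )
  unname(out)
}
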