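# Plugin registry: named constructors for extractors, selectors and
# classifiers.  Built-in algorithms are pre-registered when the package
# loads; user plugins are added with register_plugin() and become addressable
# from chain configurations by name.  Extractor plugins are contract-checked
# at first use (their output length must not depend on image content).

the_registry <- new.env(parent = emptyenv())

registry_reset <- function() {
  the_registry$extractor <- list()
  the_registry$selector <- list()
  the_registry$classifier <- list()
  register_builtin_extractors()
}

registry_get <- function(kind, name) {
  the_registry[[kind]][[name]]
}

#' Register an algorithm plugin
#'
#' Adds an extractor, selector or classifier under a new name, making it
#' addressable from algorithm chains and chain configuration files.
#'
#' * extractor constructor: `function(params)` returning
#'   `function(volume) -> numeric vector` (fixed length for a given
#'   configuration; checked at first use).
#' * selector: `function(x, labels) -> numeric scores`, one per column.
#' * classifier: a list with `fit(x, y, params)` and
#'   `predict(fit, newdata) -> labels`.
#'
#' @param kind `"extractor"`, `"selector"` or `"classifier"`.
#' @param name plugin name; registering an existing name is an error.
#' @param constructor the plugin implementation (see above).
#' @return `name`, invisibly.
#' @export
register_plugin <- function(kind, name, constructor) {
  kind <- match.arg(kind, c("extractor", "selector", "classifier"))
  if (!is.null(registry_get(kind, name)) ||
      (kind == "classifier" && name %in% CLASSIFIER_KINDS) ||
      (kind == "selector" && name == "fisher")) {
    stop_config("a ", kind, " named '", name, "' is already registered")
  }
  the_registry[[kind]][[name]] <- constructor
  invisible(name)
}

#' List registered plugins
#'
#' @return Named list of character vectors (registered names per kind).
#' @export
list_plugins <- function() {
  list(
    extractor = names(the_registry$extractor),
    selector = c("fisher", names(the_registry$selector)),
    classifier = c(CLASSIFIER_KINDS, names(the_registry$classifier))
  )
}

# ---- built-in extractors ----------------------------------------------------

# Each built-in constructor takes the extractor's parameter list and returns
# a function(volume) -> named numeric vector.
register_builtin_extractors <- function() {
  b <- list(
    "haar2d" = function(p) {
      levels <- p$levels %||% 2L
      pooling <- p$pooling %||% "stats"
      function(v) features_haar_2d(v, levels = levels, pooling = pooling)
    },
    "aniso-wavelet-3d" = function(p) {
      levels <- p$levels %||% 2L
      sigma <- p$sigma
      function(v) features_aniso_wavelet_3d(v, levels = levels, sigma = sigma)
    },
    "hu-2d" = function(p) function(v) hu_moments_2d(v),
    "hu-3d" = function(p) function(v) hu_moments_3d(v),
    "zernike" = function(p) {
      count <- p$count %||% 20L
      function(v) zernike_moments(v, count = count)
    },
    "object-statistics" = function(p) {
      threshold <- p$threshold %||% "otsu"
      function(v) object_statistics(segment_objects(v, threshold))
    },
    "object-territory" = function(p) {
      threshold <- p$threshold %||% "otsu"
      function(v) object_territory(segment_objects(v, threshold))
    },
    "differential" = function(p) {
      scales <- p$scales %||% c(1, 2)
      function(v) differential_features(v, scales = scales, pooling = "image-stats")
    }
  )
  the_registry$extractor <- b
}

resolve_extractor <- function(spec) {
  ctor <- registry_get("extractor", spec$name)
  if (is.null(ctor)) {
    stop_config("unknown extractor '", spec$name, "'; registered extractors: ",
                paste(names(the_registry$extractor), collapse = ", "))
  }
  ctor(spec$params %||% spec)
}

.onLoad <- function(libname, pkgname) {
  registry_reset()
}
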