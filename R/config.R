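# Chain configuration files: one JSON document defines a full comparison
# experiment (chains, evaluation protocol, input description).  Unknown keys
# are rejected with their location so typos cannot silently change an
# experiment.

check_keys <- function(node, allowed, where) {
  unknown <- setdiff(names(node), allowed)
  if (length(unknown) > 0L) {
    stop_config("unknown key(s) ", paste0("'", unknown, "'", collapse = ", "),
                " at ", where, " (allowed: ", paste(allowed, collapse = ", "), ")")
  }
}

parse_extractor <- function(node, where) {
  if (is.null(node[["name"]])) stop_config("extractor at ", where, " needs a 'name'")
  params <- node[setdiff(names(node), "name")]
  do.call(extractor_spec, c(list(name = node[["name"]]), params))
}

parse_selector <- function(node, where) {
  check_keys(node, c("criterion", "n_keep"), where)
  if (is.null(node$n_keep)) stop_config("selector at ", where, " needs 'n_keep'")
  selector_spec(criterion = node$criterion %||% "fisher", n_keep = node$n_keep)
}

parse_classifier <- function(node, where) {
  check_keys(node, c("kind", "k", "cost", "ntree", "maxdepth", "scale",
                     "seed", "params"), where)
  if (is.null(node[["kind"]])) stop_config("classifier at ", where, " needs a 'kind'")
  # note [[: $ would partially match e.g. node$k against node$kind
  classifier_spec(
    kind = node[["kind"]],
    k = node[["k"]] %||% 3L,
    cost = node[["cost"]] %||% 1,
    ntree = node[["ntree"]] %||% 100L,
    maxdepth = node[["maxdepth"]],
    scale = node[["scale"]] %||% FALSE,
    seed = node[["seed"]] %||% 1L,
    params = node[["params"]] %||% list()
  )
}

parse_chain <- function(node, where) {
  check_keys(node, c("name", "extractors", "selectors", "classifier"), where)
  if (length(node$extractors) == 0L) {
    stop_config("chain at ", where, " needs at least one extractor")
  }
  if (is.null(node$classifier)) {
    stop_config("chain at ", where, " needs a classifier")
  }
  algorithm_chain(
    extractors = lapply(seq_along(node$extractors), function(i) {
      parse_extractor(node$extractors[[i]],
                      sprintf("%s$extractors[[%d]]", where, i))
    }),
    selectors = lapply(seq_along(node$selectors), function(i) {
      parse_selector(node$selectors[[i]],
                     sprintf("%s$selectors[[%d]]", where, i))
    }),
    classifier = parse_classifier(node$classifier,
                                  paste0(where, "$classifier")),
    name = node$name
  )
}

#' Parse a chain configuration file
#'
#' A single JSON document describing a comparison experiment: a list of
#' chains, the evaluation protocol, and the input (label-source) description.
#' Unknown keys are rejected with their location.
#'
#' @param path path to the JSON config, or an already-parsed list.
#' @return A list with `chains` (list of [algorithm_chain()]),
#'   `protocol` (an [eval_protocol()]) and `io` (the label-source spec).
#' @export
parse_chain_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop_config("config file not found: ", path)
    tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
      error = function(e) stop_config("cannot parse config '", path, "': ",
                                      conditionMessage(e)))
  } else {
    path
  }
  check_keys(cfg, c("chains", "protocol", "io"), "top level")
  if (length(cfg$chains) == 0L) stop_config("config lists no chains")
  chains <- lapply(seq_along(cfg$chains), function(i) {
    parse_chain(cfg$chains[[i]], sprintf("chains[[%d]]", i))
  })
  proto <- cfg$protocol %||% list()
  check_keys(proto, c("folds", "repeats", "seed", "stratified"), "protocol")
  protocol <- eval_protocol(
    folds = proto$folds %||% 5L,
    repeats = proto$repeats %||% 5L,
    seed = proto$seed %||% 1L,
    stratified = proto$stratified %||% TRUE
  )
  io <- cfg$io %||% list()
  check_keys(io, c("mode", "path", "image", "roi_files", "channel",
                   "geometry", "interval"), "io")
  if (!is.null(io$geometry)) {
    check_keys(io$geometry, c("rx", "ry", "rz"), "io$geometry")
    io$geometry <- patch_geometry(io$geometry$rx, io$geometry$ry,
                                  io$geometry$rz %||% 0L)
  }
  if (!is.null(io$roi_files)) io$roi_files <- unlist(io$roi_files)
  list(chains = chains, protocol = protocol, io = io)
}
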