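#' Read and write decision trees as JSON
#'
#' Strategies are stored as a JSON object keyed by strategy label, each
#' with `upfront_cost` and a recursive `root` node:
#' `{"type": "chance", "branches": [{"p": 0.7, "node": {...}}]}` or
#' `{"type": "terminal", "cost": 1000, "effect": 1.5}`. Trees are
#' validated on load.
#'
#' @param strategies A list of `fp_strategy` objects.
#' @param path File path.
#' @return `read_strategies()` returns a named list of validated
#'   `fp_strategy` objects; `write_strategies()` returns `path` invisibly.
#' @export
write_strategies <- function(strategies, path) {
  if (inherits(strategies, "fp_strategy")) strategies <- list(strategies)
  payload <- stats::setNames(
    lapply(strategies, function(s) {
      list(upfront_cost = s$upfront_cost, root = node_to_list(s$root))
    }),
    vapply(strategies, function(s) s$label, character(1))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_strategies
#' @export
read_strategies <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  strategies <- lapply(names(payload), function(label) {
    raw <- payload[[label]]
    s <- strategy(
      label = label,
      root = node_from_list(raw$root),
      upfront_cost = raw$upfront_cost %||% 0
    )
    stop_if_invalid(s)
    s
  })
  stats::setNames(strategies, names(payload))
}

node_to_list <- function(node) {
  if (node$type == "terminal") {
    list(type = "terminal", cost = node$cost, effect = node$effect)
  } else {
    list(type = "chance", branches = lapply(node$branches, function(b) {
      list(p = b$p, node = node_to_list(b$node))
    }))
  }
}

node_from_list <- function(x) {
  if (is.null(x$type)) stop("tree node has no 'type' field", call. = FALSE)
  if (x$type == "terminal") {
    terminal_node(cost = as.numeric(x$cost), effect = as.numeric(x$effect))
  } else if (x$type == "chance") {
    chance_node(lapply(x$branches, function(b) {
      branch(as.numeric(b$p), node_from_list(b$node))
    }))
  } else {
    stop(sprintf("unknown node type '%s' in tree document", x$type),
      call. = FALSE
    )
  }
}
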