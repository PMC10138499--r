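#' @title Pattern-query language
#' @description
#' Queries are JSON documents with exactly two top-level segments:
#' `"match"`, listing the searched entities and the relations between
#' them, and `"params"`, listing attribute conditions on those entities
#' and relations. Concretely:
#'
#' ```json
#' {
#'   "match": {
#'     "nodes": {"g": "gene", "d": "disease"},
#'     "relations": [
#'       {"from": "g", "label": "RELATED_WITH", "to": "d",
#'        "direction": "out", "alias": "r1"}
#'     ]
#'   },
#'   "params": {
#'     "r1": [{"target": "prop.score", "op": "gte", "value": 0.5}]
#'   }
#' }
#' ```
#'
#' Node aliases map to entity types; each relation entry names a label
#' (or `"ANY"`), a direction (`"out"` = from→to as stored, `"any"` =
#' either way) and an optional edge alias usable in `"params"`. Condition
#' targets are `primary_id`, `identifier`,
#' `data.<source_label>.<key>` (node aliases) or `prop.<key>` (edge
#' aliases); operators are `eq, ne, gt, gte, lt, lte, contains`.
#' @name query-language
NULL

BG_CONDITION_OPS <- c("eq", "ne", "gt", "gte", "lt", "lte", "contains")

validate_condition <- function(cond, alias, is_edge) {
  for (f in c("target", "op"))
    if (is.null(cond[[f]]))
      stop_validation("condition on alias '%s' is missing '%s'", alias, f)
  if (!"value" %in% names(cond))
    stop_validation("condition on alias '%s' is missing 'value'", alias)
  op <- cond$op
  if (!op %in% BG_CONDITION_OPS)
    stop_validation("unknown op '%s' on alias '%s'; allowed ops: %s",
                    op, alias, paste(BG_CONDITION_OPS, collapse = ", "))
  target <- cond$target
  is_prop <- grepl("^prop\\.[^.]+$", target)
  is_data <- grepl("^data\\.[^.]+\\.[^.]+$", target)
  is_plain <- target %in% c("primary_id", "identifier")
  if (!is_prop && !is_data && !is_plain)
    stop_validation(paste0("bad condition target '%s' on alias '%s'; expected ",
                           "primary_id, identifier, data.<source>.<key> or prop.<key>"),
                    target, alias)
  if (is_edge && !is_prop)
    stop_validation("edge alias '%s' only admits prop.<key> targets", alias)
  if (!is_edge && is_prop)
    stop_validation("prop.<key> target is only valid on edge aliases (alias '%s')",
                    alias)
  v <- cond$value
  if (!is_scalar_value(v))
    stop_validation("condition value on alias '%s' must be a scalar", alias)
  if (op %in% c("gt", "gte", "lt", "lte") && !is.numeric(v))
    stop_validation("ordering op '%s' on alias '%s' requires a numeric value",
                    op, alias)
  if (op == "contains" && !is.character(v))
    stop_validation("'contains' on alias '%s' requires a string value", alias)
  list(target = target, op = op, value = v)
}

#' Parse a JSON pattern query
#'
#' Accepts a JSON string, a file path, or an already-decoded list, and
#' returns a validated `bg_query`. The pattern must be nonempty and
#' connected, aliases must be unique, and every alias used in `"params"`
#' must be declared in `"match"`.
#'
#' @param text JSON string, path to a JSON file, or list.
#' @return A `bg_query` with elements `nodes` (alias → entity type),
#'   `edges` (list of from/label/to/direction/alias) and `conditions`
#'   (alias → list of conditions).
#' @export
bg_parse_query <- function(text) {
  if (is.character(text)) {
    stopifnot(length(text) == 1L)
    if (file.exists(text) && !grepl("[{\n]", text)) text <- readLines(text, warn = FALSE)
    doc <- tryCatch(
      jsonlite::fromJSON(paste(text, collapse = "\n"), simplifyVector = FALSE),
      error = function(e) stop("query parse error: ", conditionMessage(e),
                               call. = FALSE))
  } else if (is.list(text)) {
    doc <- text
  } else stop_validation("query must be a JSON string, file path or list")

  extra <- setdiff(names(doc), c("match", "params"))
  if (length(extra))
    stop_validation("unknown top-level keys: %s (only 'match' and 'params' are allowed)",
                    paste(extra, collapse = ", "))
  if (is.null(doc$match) || length(doc$match) == 0L)
    stop_validation("empty pattern: 'match' segment is required and nonempty")
  match_ <- doc$match
  nodes_in <- match_$nodes
  if (is.null(nodes_in) || length(nodes_in) == 0L)
    stop_validation("empty pattern: 'match.nodes' must declare at least one alias")
  aliases <- names(nodes_in)
  if (is.null(aliases) || any(!nzchar(aliases)) || anyDuplicated(aliases))
    stop_validation("node aliases must be unique nonempty names")
  nodes <- vapply(nodes_in, function(t) {
    if (!is.character(t) || !nzchar(bg_trim(t)))
      stop_validation("entity type must be a nonempty string")
    tolower(bg_trim(t))
  }, character(1))

  rel_in <- match_$relations %||% list()
  edges <- list()
  edge_aliases <- character(0)
  for (i in seq_along(rel_in)) {
    e <- rel_in[[i]]
    for (f in c("from", "to"))
      if (is.null(e[[f]]) || !e[[f]] %in% aliases)
        stop_validation("relation %d: '%s' must name a declared node alias", i, f)
    label <- if (is.null(e$label) || identical(toupper(e$label), "ANY")) "ANY"
             else bg_normalize_label(e$label)
    direction <- e$direction %||% "out"
    if (!direction %in% c("out", "any"))
      stop_validation("relation %d: direction must be 'out' or 'any'", i)
    alias <- e$alias %||% sprintf("..e%d", i)
    edges[[i]] <- list(from = e$from, label = label, to = e$to,
                       direction = direction, alias = alias)
    edge_aliases <- c(edge_aliases, alias)
  }
  if (anyDuplicated(edge_aliases) || length(intersect(edge_aliases, aliases)))
    stop_validation("edge aliases must be unique and distinct from node aliases")

  # connectivity over node aliases
  if (length(aliases) > 1L) {
    comp <- stats::setNames(seq_along(aliases), aliases)
    for (e in edges) {
      a <- comp[[e$from]]; b <- comp[[e$to]]
      if (a != b) comp[comp == b] <- a
    }
    if (length(unique(comp)) > 1L)
      stop_validation("pattern is disconnected: aliases %s are not linked to the rest",
                      paste(names(comp)[comp != comp[[1]]], collapse = ", "))
  }

  conditions <- list()
  params <- doc$params %||% list()
  if (length(params)) {
    for (alias in names(params)) {
      if (!alias %in% c(aliases, edge_aliases))
        stop_validation("params reference unknown alias '%s'", alias)
      conds <- params[[alias]]
      if (!is.list(conds)) stop_validation("params for alias '%s' must be a list", alias)
      if (length(conds) && !is.null(names(conds)) && any(nzchar(names(conds))))
        conds <- list(conds)  # single condition object given directly
      conditions[[alias]] <- lapply(conds, validate_condition, alias = alias,
                                    is_edge = alias %in% edge_aliases)
    }
  }
  structure(list(nodes = nodes, edges = edges, conditions = conditions),
            class = "bg_query")
}

#' @export
print.bg_query <- function(x, ...) {
  cat(sprintf("<query: %d nodes, %d relations, %d conditioned aliases>\n",
              length(x$nodes), length(x$edges), length(x$conditions)))
  invisible(x)
}

query_to_list <- function(pattern) {
  rels <- lapply(seq_along(pattern$edges), function(i) {
    e <- pattern$edges[[i]]
    out <- list(from = e$from, label = e$label, to = e$to,
                direction = e$direction)
    if (!grepl("^\\.\\.e[0-9]+$", e$alias)) out$alias <- e$alias
    out
  })
  list(match = list(nodes = as.list(pattern$nodes), relations = rels),
       params = if (length(pattern$conditions)) pattern$conditions
                else structure(list(), names = character(0)))
}

#' Save / load a query as JSON
#'
#' Saved files are exactly the documents [bg_parse_query()] accepts, so
#' queries can be shared between machines; save → load round-trips to an
#' equal pattern.
#'
#' @param pattern A `bg_query`.
#' @param path File path.
#' @return `bg_save_query` returns `path` invisibly; `bg_load_query`
#'   returns the parsed `bg_query`.
#' @export
bg_save_query <- function(pattern, path) {
  stopifnot(inherits(pattern, "bg_query"))
  writeLines(jsonlite::toJSON(query_to_list(pattern), auto_unbox = TRUE,
                              digits = NA, pretty = TRUE), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname bg_save_query
#' @export
bg_load_query <- function(path) {
  if (!file.exists(path)) stop("query file not found: ", path, call. = FALSE)
  bg_parse_query(paste(readLines(path, warn = FALSE), collapse = "\n"))
}
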