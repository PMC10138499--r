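#' @title Query execution
#' @description
#' A parsed pattern is matched against the graph by backtracking search:
#' node aliases are bound to stored entities of the required type —
#' injectively, distinct aliases bind distinct entities — and every
#' pattern relation must map to a distinct stored relation with the right
#' label, direction and endpoints, with all conditions satisfied. Because
#' matched patterns are often branching rather than linear, each match is
#' decomposed into linear edge-disjoint paths for display and export.
#' @name query-execution
NULL

cond_numeric <- function(x) {
  if (is.numeric(x)) x
  else if (is.logical(x)) as.numeric(x)
  else NA_real_
}

apply_op <- function(op, stored, wanted) {
  if (op %in% c("gt", "gte", "lt", "lte")) {
    s <- cond_numeric(stored)
    if (is.na(s)) {
      warning("ordering comparison against non-numeric stored value; condition is false",
              call. = FALSE)
      return(FALSE)
    }
    return(switch(op, gt = s > wanted, gte = s >= wanted,
                  lt = s < wanted, lte = s <= wanted))
  }
  if (op == "contains") {
    if (!is.character(stored)) return(FALSE)
    return(grepl(tolower(wanted), tolower(stored), fixed = TRUE))
  }
  # eq / ne; strings compare case-insensitively
  eq <- if (is.character(stored) && is.character(wanted))
    tolower(stored) == tolower(wanted)
  else if (is.numeric(stored) || is.logical(stored))
    isTRUE(cond_numeric(stored) == cond_numeric(wanted))
  else identical(stored, wanted)
  if (op == "eq") eq else !eq
}

#' Evaluate one condition against a bound entity or relation
#'
#' `primary_id` and `identifier` targets test the entity's primary
#' identifier and (for `identifier`) every HAS_ID-linked identifier
#' value, case-insensitively. `data.<source>.<key>` targets resolve
#' through the entity's HAS_DATA objects with that source label and hold
#' if any of them satisfies the comparison. `prop.<key>` reads a
#' relation's properties. A missing attribute makes the condition false,
#' never an error; ordering comparisons against non-numeric stored values
#' are false with a warning.
#'
#' @param db A `bg_db`.
#' @param condition Validated condition (target/op/value).
#' @param subject_id ObjectID of the bound entity or relation.
#' @param kind "entity" or "relation".
#' @return Logical scalar.
#' @export
bg_evaluate_condition <- function(db, condition, subject_id,
                                  kind = c("entity", "relation")) {
  kind <- match.arg(kind)
  target <- condition$target
  op <- condition$op
  wanted <- condition$value
  if (kind == "relation") {
    key <- sub("^prop\\.", "", target)
    rel <- get(subject_id, envir = db$edges, inherits = FALSE)
    stored <- rel$props[[key]]
    if (is.null(stored)) return(FALSE)
    return(apply_op(op, stored, wanted))
  }
  entity <- bg_get(db, subject_id)
  if (target == "primary_id")
    return(apply_op(op, entity$primary_identifier, wanted))
  if (target == "identifier") {
    values <- entity$primary_identifier
    for (nb in bg_neighbors(db, subject_id, label = "HAS_ID", direction = "out"))
      values <- c(values, nb$neighbor$value)
    return(any(vapply(values, apply_op, logical(1), op = op, wanted = wanted)))
  }
  parts <- strsplit(target, ".", fixed = TRUE)[[1]]
  src <- parts[2]; key <- paste(parts[-(1:2)], collapse = ".")
  for (nb in bg_neighbors(db, subject_id, label = "HAS_DATA", direction = "out")) {
    if (nb$neighbor$source_label != src) next
    stored <- nb$neighbor$payload[[key]]
    if (!is.null(stored) && apply_op(op, stored, wanted)) return(TRUE)
  }
  FALSE
}

node_conditions_hold <- function(db, pattern, alias, entity_id) {
  conds <- pattern$conditions[[alias]]
  if (is.null(conds)) return(TRUE)
  for (cond in conds)
    if (!bg_evaluate_condition(db, cond, entity_id, "entity")) return(FALSE)
  TRUE
}

# stored relation ids between two bound entities satisfying an edge spec
edge_candidates <- function(db, spec, from_id, to_id, pattern) {
  out <- character(0)
  eids <- if (exists(from_id, envir = db$adj_out, inherits = FALSE))
    get(from_id, envir = db$adj_out, inherits = FALSE) else character(0)
  if (spec$direction == "any") {
    eids <- c(eids, if (exists(from_id, envir = db$adj_in, inherits = FALSE))
      get(from_id, envir = db$adj_in, inherits = FALSE) else character(0))
  }
  for (eid in sort(unique(eids), method = "radix")) {
    rel <- get(eid, envir = db$edges, inherits = FALSE)
    if (rel$label %in% c("HAS_ID", "HAS_DATA")) next
    if (spec$label != "ANY" && rel$label != spec$label) next
    forward <- rel$source_id == from_id && rel$target_id == to_id
    backward <- rel$source_id == to_id && rel$target_id == from_id
    if (!(forward || (spec$direction == "any" && backward))) next
    ok <- TRUE
    for (cond in pattern$conditions[[spec$alias]] %||% list())
      if (!bg_evaluate_condition(db, cond, eid, "relation")) { ok <- FALSE; break }
    if (ok) out <- c(out, eid)
  }
  unique(out)
}

#' Execute a pattern query
#'
#' Returns every injective binding of the pattern's node aliases to
#' stored entities of the required types such that each pattern relation
#' maps to a distinct stored relation with matching label and direction
#' and all conditions hold. The search binds the most-constrained alias
#' (fewest surviving candidates) first; results are sorted by their
#' binding tuple, so runs are deterministic. An empty result list is a
#' valid outcome.
#'
#' @param db A `bg_db`.
#' @param pattern A `bg_query` from [bg_parse_query()].
#' @return List of `bg_match` objects, each with `binding` (alias →
#'   entity ObjectID) and `edges` (edge alias → relation ObjectID).
#' @export
bg_execute <- function(db, pattern) {
  stopifnot(inherits(pattern, "bg_query"))
  aliases <- names(pattern$nodes)
  candidates <- lapply(aliases, function(a) {
    ids <- bg_entities(db, pattern$nodes[[a]])
    ids[vapply(ids, function(i) node_conditions_hold(db, pattern, a, i),
               logical(1))]
  })
  names(candidates) <- aliases
  if (any(vapply(candidates, length, 0L) == 0L)) return(list())
  order_aliases <- aliases[order(vapply(candidates, length, 0L),
                                 aliases, method = "radix")]
  results <- list()
  binding <- character(0)

  assign_nodes <- function(pos) {
    if (pos > length(order_aliases)) {
      assign_edges(1L, character(0))
      return(invisible(NULL))
    }
    alias <- order_aliases[[pos]]
    for (ent in candidates[[alias]]) {
      if (ent %in% binding) next  # injectivity
      binding[[alias]] <<- ent
      ok <- TRUE
      for (spec in pattern$edges) {
        if (!(spec$from %in% names(binding)) || !(spec$to %in% names(binding)))
          next
        if (length(edge_candidates(db, spec, binding[[spec$from]],
                                   binding[[spec$to]], pattern)) == 0L) {
          ok <- FALSE; break
        }
      }
      if (ok) assign_nodes(pos + 1L)
      binding <<- binding[names(binding) != alias]
    }
    invisible(NULL)
  }

  assign_edges <- function(ei, used) {
    if (ei > length(pattern$edges)) {
      m <- structure(list(binding = binding[aliases],
                          edges = stats::setNames(used,
                            vapply(pattern$edges, `[[`, "", "alias"))),
                     class = "bg_match")
      results[[length(results) + 1L]] <<- m
      return(invisible(NULL))
    }
    spec <- pattern$edges[[ei]]
    for (eid in edge_candidates(db, spec, binding[[spec$from]],
                                binding[[spec$to]], pattern)) {
      if (eid %in% used) next  # pattern edges map to distinct relations
      assign_edges(ei + 1L, c(used, eid))
    }
    invisible(NULL)
  }

  assign_nodes(1L)
  if (length(results) > 1L) {
    keys <- vapply(results, function(m)
      paste(c(m$binding, m$edges), collapse = "|"), character(1))
    results <- results[order(keys, method = "radix")]
  }
  results
}

#' @export
print.bg_match <- function(x, ...) {
  cat("<match:", paste(sprintf("%s=%s", names(x$binding),
                               substr(x$binding, 1, 8)), collapse = " "), ">\n")
  invisible(x)
}

#' Decompose a match into linear edge-disjoint paths
#'
#' The matched subgraph (bound entities plus bound relations, taken as an
#' undirected multigraph) is peeled into maximal trails: while edges
#' remain, start from the odd-degree vertex with the smallest ObjectID
#' (or the smallest-ID vertex with edges left, if none is odd) and walk
#' unused edges, always taking the smallest unused incident relation ID.
#' The returned paths are pairwise edge-disjoint and together cover every
#' matched edge exactly once; for tree-shaped matches the number of paths
#' is the minimum possible, half the number of odd-degree vertices.
#'
#' @param db A `bg_db`.
#' @param match A `bg_match` from [bg_execute()].
#' @return List of `bg_path` objects, each an alternating sequence stored
#'   as `nodes` (entity IDs, length k+1) and `edges` (relation IDs,
#'   length k).
#' @export
bg_decompose_paths <- function(db, match) {
  stopifnot(inherits(match, "bg_match"))
  edge_ids <- sort(unique(unname(match$edges)), method = "radix")
  if (length(edge_ids) == 0L) return(list())
  ends <- lapply(edge_ids, function(eid) {
    rel <- get(eid, envir = db$edges, inherits = FALSE)
    c(rel$source_id, rel$target_id)
  })
  names(ends) <- edge_ids
  unused <- stats::setNames(rep(TRUE, length(edge_ids)), edge_ids)
  degree_of <- function(v) sum(vapply(edge_ids[unused], function(e)
    sum(ends[[e]] == v), 0L))
  paths <- list()
  while (any(unused)) {
    verts <- sort(unique(unlist(ends[edge_ids[unused]], use.names = FALSE)),
                  method = "radix")
    degs <- vapply(verts, degree_of, 0L)
    odd <- verts[degs %% 2L == 1L]
    start <- if (length(odd)) odd[[1]] else verts[[1]]
    nodes <- start
    path_edges <- character(0)
    current <- start
    repeat {
      inc <- edge_ids[unused]
      inc <- inc[vapply(inc, function(e) current %in% ends[[e]], logical(1))]
      if (length(inc) == 0L) break
      eid <- sort(inc, method = "radix")[[1]]
      unused[[eid]] <- FALSE
      pair <- ends[[eid]]
      current <- if (pair[[1]] == current) pair[[2]] else pair[[1]]
      path_edges <- c(path_edges, eid)
      nodes <- c(nodes, current)
    }
    paths[[length(paths) + 1L]] <-
      structure(list(nodes = nodes, edges = path_edges), class = "bg_path")
  }
  paths
}

#' @export
print.bg_path <- function(x, ...) {
  cat("<path:", length(x$edges), "edges>\n")
  invisible(x)
}

path_cells <- function(db, path) {
  out <- character(0)
  for (i in seq_along(path$edges)) {
    ent <- bg_get(db, path$nodes[[i]])
    rel <- bg_get(db, path$edges[[i]])
    out <- c(out, ent$primary_identifier, rel$label)
  }
  last <- bg_get(db, path$nodes[[length(path$nodes)]])
  c(out, last$primary_identifier)
}

#' Export query results
#'
#' CSV (RFC-4180 quoting) has one row per (match, path): `match_index`,
#' `path_index`, then alternating node primary-identifier and relation
#' label cells (`node_1, relation_1, node_2, ...`), padded with empty
#' cells to the longest path. JSON mirrors the full binding structure
#' (entity types, primary identifiers, ObjectIDs, edge bindings, paths)
#' and re-reads to the same bindings via [bg_read_results()].
#'
#' @param db A `bg_db`.
#' @param matches List of `bg_match` from [bg_execute()].
#' @param path Output file path.
#' @param format "csv" or "json".
#' @return `path`, invisibly.
#' @export
bg_export_results <- function(db, matches, path, format = c("csv", "json")) {
  format <- match.arg(format)
  decomposed <- lapply(matches, function(m) bg_decompose_paths(db, m))
  if (format == "csv") {
    rows <- list()
    for (mi in seq_along(matches))
      for (pi in seq_along(decomposed[[mi]]))
        rows[[length(rows) + 1L]] <-
          c(match_index = mi, path_index = pi,
            cells = path_cells(db, decomposed[[mi]][[pi]]))
    width <- if (length(rows)) max(vapply(rows, length, 0L)) - 2L else 1L
    n_nodes <- ceiling((width + 1L) / 2L)
    header <- c("match_index", "path_index",
                head(as.vector(rbind(paste0("node_", seq_len(n_nodes)),
                                     paste0("relation_", seq_len(n_nodes)))),
                     width))
    con <- file(path, "wb")
    on.exit(close(con))
    csv_quote <- function(x) paste0('"', gsub('"', '""', x), '"')
    writeLines(paste(csv_quote(header), collapse = ","), con, useBytes = TRUE)
    for (r in rows) {
      cells <- c(r[1:2], r[-(1:2)], rep("", width - (length(r) - 2L)))
      writeLines(paste(csv_quote(cells), collapse = ","), con, useBytes = TRUE)
    }
    return(invisible(path))
  }
  out <- lapply(seq_along(matches), function(mi) {
    m <- matches[[mi]]
    list(
      binding = lapply(stats::setNames(names(m$binding), names(m$binding)),
        function(a) {
          ent <- bg_get(db, m$binding[[a]])
          list(entity_type = ent$entity_type,
               primary_identifier = ent$primary_identifier,
               id = m$binding[[a]])
        }),
      edges = as.list(m$edges),
      paths = lapply(decomposed[[mi]], function(p)
        list(nodes = p$nodes, edges = p$edges))
    )
  })
  jsonlite::write_json(list(results = out), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Re-read exported JSON results
#'
#' @param path File written by [bg_export_results()] with `format="json"`.
#' @return List of `bg_match` objects with the exact original bindings.
#' @export
bg_read_results <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(doc$results, function(r) {
    structure(list(
      binding = vapply(r$binding, function(b) b$id, character(1)),
      edges = vapply(r$edges, identity, character(1))
    ), class = "bg_match")
  })
}
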