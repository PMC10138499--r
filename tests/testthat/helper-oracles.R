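# Independent oracles and random-instance generators shared by the suite.
# Oracles deliberately avoid the code paths they check: the matcher oracle
# enumerates assignments by brute force over full edge scans, the path-cover
# oracle is a shortest-path search over (covered-edge-set, trail-end) states,
# and the keyword oracle is a naive scan over recorded token lists.

ENTITY_TYPES <- c("gene", "protein", "disease", "antigen", "epitope")

rand_string <- function(len = 6, chars = c(LETTERS, 0:9)) {
  paste(sample(chars, len, replace = TRUE), collapse = "")
}

rand_entity <- function() bg_entity(sample(ENTITY_TYPES, 1), rand_string())

rand_payload <- function(n_keys = sample(1:4, 1)) {
  keys <- unique(replicate(n_keys, rand_string(4, letters)))
  vals <- lapply(seq_along(keys), function(i)
    switch(sample(3, 1), rand_string(), round(stats::runif(1) * 100, 3),
           sample(c(TRUE, FALSE), 1)))
  stats::setNames(vals, keys)
}

rand_object <- function() {
  switch(sample(4, 1),
    rand_entity(),
    bg_identifier(sample(c("name", "url", "id"), 1), rand_string(5), rand_string()),
    bg_data(rand_string(5, letters), rand_payload()),
    {
      a <- bg_id(rand_entity()); b <- bg_id(rand_entity())
      while (identical(a, b)) b <- bg_id(rand_entity())
      bg_relation(sample(BG_BASE_RELATIONS, 1), a, b, rand_payload(sample(0:2, 1)))
    })
}

# -- random stores and patterns ----------------------------------------------

# small typed store: entities, entity-entity edges with score props, and
# disorder-content data objects so node conditions have something to test
rand_store <- function(n_entities = sample(5:40, 1), edge_factor = 1.5) {
  db <- bg_db()
  txn <- bg_begin(db)
  ids <- character(0)
  for (i in seq_len(n_entities)) {
    e <- bg_entity(sample(ENTITY_TYPES, 1), sprintf("E%03d_%s", i, rand_string(3)))
    res <- bg_upsert(db, e)
    ids <- c(ids, res$id)
    if (stats::runif(1) < 0.4)
      bg_upsert_relation(db, bg_relation(
        "HAS_DATA", res$id,
        bg_upsert(db, bg_data("disprot",
          list(disorder_content = round(stats::runif(1), 2))))$id))
  }
  n_edges <- ceiling(n_entities * edge_factor)
  for (i in seq_len(n_edges)) {
    ab <- sample(ids, 2)
    rel <- bg_relation(sample(BG_BASE_RELATIONS, 1), ab[[1]], ab[[2]],
                       if (stats::runif(1) < 0.7)
                         list(score = round(stats::runif(1), 2)) else list())
    bg_upsert_relation(db, rel)
  }
  bg_commit(txn)
  db
}

rand_pattern <- function(n_nodes = sample(2:5, 1, prob = c(0.3, 0.3, 0.3, 0.1))) {
  aliases <- paste0("n", seq_len(n_nodes))
  nodes <- stats::setNames(as.list(sample(ENTITY_TYPES, n_nodes, replace = TRUE)),
                           aliases)
  rels <- list()
  for (i in seq_len(n_nodes)[-1]) {  # spanning tree keeps the pattern connected
    j <- sample(i - 1L, 1)
    rels[[length(rels) + 1L]] <- list(
      from = aliases[[j]], to = aliases[[i]],
      label = sample(c(BG_BASE_RELATIONS, "ANY"), 1),
      direction = sample(c("out", "any"), 1),
      alias = paste0("r", length(rels) + 1L))
  }
  params <- list()
  for (r in rels)
    if (stats::runif(1) < 0.4)
      params[[r$alias]] <- list(list(target = "prop.score",
                                     op = sample(c("gte", "gt", "lte"), 1),
                                     value = round(stats::runif(1), 2)))
  for (a in aliases)
    if (stats::runif(1) < 0.3)
      params[[a]] <- list(list(target = "data.disprot.disorder_content",
                               op = "gte", value = round(stats::runif(1), 2)))
  bg_parse_query(list(match = list(nodes = nodes, relations = rels),
                      params = params))
}

# -- brute-force matcher oracle ----------------------------------------------

oracle_edge_table <- function(db) {
  ids <- bg_edges(db)
  lapply(stats::setNames(ids, ids), function(i) bg_get(db, i))
}

oracle_node_cond <- function(db, cond, ent_id) {
  parts <- strsplit(cond$target, ".", fixed = TRUE)[[1]]
  stopifnot(parts[1] == "data")
  vals <- c()
  for (eid in bg_edges(db)) {
    rel <- bg_get(db, eid)
    if (rel$label == "HAS_DATA" && rel$source_id == ent_id) {
      d <- bg_get(db, rel$target_id)
      if (d$source_label == parts[2] && !is.null(d$payload[[parts[3]]]))
        vals <- c(vals, d$payload[[parts[3]]])
    }
  }
  if (length(vals) == 0) return(FALSE)
  any(switch(cond$op, gte = vals >= cond$value, gt = vals > cond$value,
             lte = vals <= cond$value, lt = vals < cond$value,
             eq = vals == cond$value, ne = vals != cond$value))
}

oracle_edge_cond <- function(cond, rel) {
  key <- sub("^prop\\.", "", cond$target)
  v <- rel$props[[key]]
  if (is.null(v) || !is.numeric(v)) return(FALSE)
  switch(cond$op, gte = v >= cond$value, gt = v > cond$value,
         lte = v <= cond$value, lt = v < cond$value,
         eq = v == cond$value, ne = v != cond$value)
}

match_key <- function(binding, edge_ids) {
  paste(c(binding, edge_ids), collapse = "|")
}

oracle_execute <- function(db, pattern) {
  aliases <- names(pattern$nodes)
  etab <- oracle_edge_table(db)
  cands <- lapply(aliases, function(a) {
    ids <- bg_entities(db, pattern$nodes[[a]])
    conds <- pattern$conditions[[a]]
    if (!is.null(conds))
      ids <- ids[vapply(ids, function(i)
        all(vapply(conds, oracle_node_cond, logical(1), db = db, ent_id = i)),
        logical(1))]
    ids
  })
  names(cands) <- aliases
  if (any(vapply(cands, length, 0L) == 0L)) return(character(0))
  grid <- expand.grid(cands, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  keys <- character(0)
  for (ri in seq_len(nrow(grid))) {
    binding <- stats::setNames(as.character(grid[ri, ]), aliases)
    if (anyDuplicated(binding)) next  # injective on entities
    per_edge <- list()
    ok <- TRUE
    for (spec in pattern$edges) {
      from <- binding[[spec$from]]; to <- binding[[spec$to]]
      hits <- character(0)
      for (eid in names(etab)) {
        rel <- etab[[eid]]
        if (rel$label %in% c("HAS_ID", "HAS_DATA")) next
        if (spec$label != "ANY" && rel$label != spec$label) next
        fwd <- rel$source_id == from && rel$target_id == to
        bwd <- rel$source_id == to && rel$target_id == from
        if (!(fwd || (spec$direction == "any" && bwd))) next
        conds <- pattern$conditions[[spec$alias]]
        if (!is.null(conds) &&
            !all(vapply(conds, oracle_edge_cond, logical(1), rel = rel))) next
        hits <- c(hits, eid)
      }
      if (length(hits) == 0L) { ok <- FALSE; break }
      per_edge[[length(per_edge) + 1L]] <- hits
    }
    if (!ok) next
    # all systems of distinct representatives over the edge-candidate sets
    pick <- function(k, used) {
      if (k > length(per_edge)) {
        keys <<- c(keys, match_key(binding, used))
        return(invisible(NULL))
      }
      for (e in per_edge[[k]]) if (!e %in% used) pick(k + 1L, c(used, e))
    }
    pick(1L, character(0))
  }
  sort(unique(keys))
}

engine_keys <- function(matches) {
  sort(vapply(matches, function(m) match_key(m$binding, unname(m$edges)),
              character(1)))
}

# -- path-cover oracle --------------------------------------------------------

# exact minimum number of edge-disjoint trails covering all edges:
# shortest-path dynamic program over states (bitmask of covered edges,
# vertex the open trail currently ends at), cost = number of trails started.
# Extending the open trail along an incident unused edge keeps the cost;
# starting a new trail (from scratch or after closing the open one) adds 1,
# which from any state is min(row) + 1 regardless of where trails ended.
oracle_min_cover <- function(ends) {
  m <- length(ends)
  verts <- sort(unique(unlist(ends)))
  nv <- length(verts)
  u <- vapply(ends, function(e) match(e[[1]], verts), 0L)
  v <- vapply(ends, function(e) match(e[[2]], verts), 0L)
  bits <- bitwShiftL(1L, 0:(m - 1L))
  n_states <- bitwShiftL(1L, m)
  INF <- m + 1L
  dist <- matrix(INF, nrow = n_states, ncol = nv)
  first <- TRUE
  for (mask in 0:(n_states - 2L)) {
    row <- dist[mask + 1L, ]
    minrow <- if (first) 0L else min(row)  # mask 0: no trail open yet
    if (minrow >= INF) { first <- FALSE; next }
    start_cost <- minrow + 1L
    free <- which(bitwAnd(mask, bits) == 0L)
    for (e in free) {
      nm <- mask + bits[[e]] + 1L
      cand_v <- min(if (first) INF else row[[u[[e]]]], start_cost)
      cand_u <- min(if (first) INF else row[[v[[e]]]], start_cost)
      if (cand_v < dist[nm, v[[e]]]) dist[nm, v[[e]]] <- cand_v
      if (cand_u < dist[nm, u[[e]]]) dist[nm, u[[e]]] <- cand_u
    }
    first <- FALSE
  }
  min(dist[n_states, ])
}

# random tree-shaped match inside a store; returns list(db, match)
rand_tree_match <- function(n_edges = sample(1:12, 1)) {
  db <- bg_db()
  txn <- bg_begin(db)
  ids <- character(n_edges + 1L)
  for (i in seq_len(n_edges + 1L))
    ids[[i]] <- bg_upsert(db, bg_entity("gene", sprintf("T%03d_%s", i, rand_string(4))))$id
  eids <- character(n_edges)
  for (i in seq_len(n_edges)) {
    parent <- ids[[sample(i, 1)]]
    eids[[i]] <- bg_upsert_relation(db, bg_relation("RELATED_WITH", parent,
                                                    ids[[i + 1L]]))$id
  }
  bg_commit(txn)
  match <- structure(list(binding = stats::setNames(ids, paste0("n", seq_along(ids))),
                          edges = stats::setNames(eids, paste0("r", seq_along(eids)))),
                     class = "bg_match")
  list(db = db, match = match)
}

odd_degree_count <- function(db, edge_ids) {
  ends <- unlist(lapply(edge_ids, function(e) {
    rel <- bg_get(db, e); c(rel$source_id, rel$target_id)
  }))
  sum(table(ends) %% 2 == 1)
}

# -- naive keyword oracle -----------------------------------------------------

# model: data.frame(token, id); exact = token match, prefix = startsWith
naive_search <- function(model, term, mode) {
  term <- tolower(term)
  hit <- if (mode == "exact") model$token == term
         else startsWith(model$token, term)
  sort(unique(model$id[hit]))
}

# -- misc ---------------------------------------------------------------------

db_fingerprint <- function(db) {
  path <- tempfile(fileext = ".jsonl")
  on.exit(unlink(path))
  bg_snapshot_write(db, path)
  readLines(path)
}
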