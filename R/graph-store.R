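#' @title Embedded graph store
#' @description
#' The knowledge graph lives in an embedded store: model objects are nodes,
#' relations are edges, all keyed by their content-derived IDs. Writes go
#' through transactions that cover the graph and the catalog index
#' together, so a failed import leaves both untouched. The store fulfils a
#' small adapter contract (upsert node, upsert edge, neighbors, stats,
#' snapshot); [bg_neo4j_adapter()] sketches where a server-backed adapter
#' would plug in.
#' @name graph-store
NULL

#' Create an empty database (graph store + catalog index)
#'
#' @return A `bg_db` object bundling the embedded graph store and the
#'   catalog database. All modifying operations require an open
#'   transaction ([bg_begin()]).
#' @examples
#' db <- bg_db()
#' txn <- bg_begin(db)
#' bg_upsert(db, bg_entity("gene", "CDKN1A"))
#' bg_commit(txn)
#' bg_stats(db)$entities
#' @export
bg_db <- function() {
  db <- new.env(parent = emptyenv())
  db$nodes <- new.env(parent = emptyenv())     # id -> list(kind, object)
  db$edges <- new.env(parent = emptyenv())     # id -> bg_relation
  db$adj_out <- new.env(parent = emptyenv())   # node id -> edge ids
  db$adj_in  <- new.env(parent = emptyenv())
  db$counts <- list(entity = 0L, identifier = 0L, data = 0L)
  db$edge_count <- 0L
  db$edges_by_label <- list()
  db$catalog <- bg_catalog_new()
  db$txn <- NULL
  class(db) <- "bg_db"
  db
}

#' @export
print.bg_db <- function(x, ...) {
  s <- bg_stats(x)
  cat(sprintf("<biograph db: %d entities, %d identifiers, %d data objects, %d relations>\n",
              s$entities, s$identifiers, s$data_objects, s$relations))
  invisible(x)
}

txn_check_open <- function(db) {
  if (is.null(db$txn) || db$txn$state != "open")
    stop("no open transaction; call bg_begin() first", call. = FALSE)
  db$txn
}

#' Transactions
#'
#' All data modification happens in transaction mode: pending writes are
#' invisible to reads until [bg_commit()], and [bg_rollback()] restores
#' the database — graph and catalog together — to its pre-transaction
#' state. Single-writer contract: only one transaction may be open.
#'
#' @param db A `bg_db`.
#' @return `bg_begin` returns a `bg_txn` handle; `bg_commit` and
#'   `bg_rollback` return the database invisibly.
#' @export
bg_begin <- function(db) {
  stopifnot(inherits(db, "bg_db"))
  if (!is.null(db$txn) && db$txn$state == "open")
    stop("a transaction is already open (single-writer contract)", call. = FALSE)
  txn <- new.env(parent = emptyenv())
  txn$state <- "open"
  txn$db <- db
  txn$pending_nodes <- list()   # id -> list(kind, object)
  txn$pending_edges <- list()   # id -> bg_relation
  txn$catalog <- bg_catalog_pending()
  class(txn) <- "bg_txn"
  db$txn <- txn
  txn
}

#' @rdname bg_begin
#' @param txn A `bg_txn` from [bg_begin()].
#' @export
bg_commit <- function(txn) {
  stopifnot(inherits(txn, "bg_txn"))
  if (txn$state != "open") stop("transaction is not open", call. = FALSE)
  db <- txn$db
  for (id in names(txn$pending_nodes)) {
    rec <- txn$pending_nodes[[id]]
    assign(id, rec, envir = db$nodes)
    db$counts[[rec$kind]] <- db$counts[[rec$kind]] + 1L
  }
  for (id in names(txn$pending_edges)) {
    rel <- txn$pending_edges[[id]]
    assign(id, rel, envir = db$edges)
    db$edge_count <- db$edge_count + 1L
    db$edges_by_label[[rel$label]] <-
      (if (is.null(db$edges_by_label[[rel$label]])) 0L else db$edges_by_label[[rel$label]]) + 1L
    adj_append(db$adj_out, rel$source_id, id)
    adj_append(db$adj_in, rel$target_id, id)
  }
  bg_catalog_apply(db$catalog, txn$catalog)
  txn$state <- "committed"
  db$txn <- NULL
  invisible(db)
}

#' @rdname bg_begin
#' @export
bg_rollback <- function(txn) {
  stopifnot(inherits(txn, "bg_txn"))
  if (txn$state != "open") stop("transaction is not open", call. = FALSE)
  db <- txn$db
  txn$state <- "rolled_back"
  db$txn <- NULL
  invisible(db)
}

adj_append <- function(adj, node_id, edge_id) {
  cur <- if (exists(node_id, envir = adj, inherits = FALSE))
    get(node_id, envir = adj, inherits = FALSE) else character(0)
  assign(node_id, c(cur, edge_id), envir = adj)
}

node_present <- function(db, id) {
  exists(id, envir = db$nodes, inherits = FALSE) ||
    (!is.null(db$txn) && db$txn$state == "open" &&
       !is.null(db$txn$pending_nodes[[id]]))
}

node_record <- function(db, id, pending_ok = FALSE) {
  if (exists(id, envir = db$nodes, inherits = FALSE))
    return(get(id, envir = db$nodes, inherits = FALSE))
  if (pending_ok && !is.null(db$txn) && db$txn$state == "open") {
    rec <- db$txn$pending_nodes[[id]]
    if (!is.null(rec)) return(rec)
  }
  NULL
}

#' Insert a model object, skipping duplicates
#'
#' Content-addresses the object and inserts it as a graph node unless a
#' node with the same ID — i.e. the same content — already exists, in
#' which case the store is unchanged. Must be called inside an open
#' transaction; the write becomes visible at commit.
#'
#' @param db A `bg_db`.
#' @param object A `bg_entity`, `bg_identifier` or `bg_data`.
#' @return List with `id` (the ObjectID) and `inserted` (logical).
#' @export
bg_upsert <- function(db, object) {
  txn <- txn_check_open(db)
  kind <- bg_kind(object)
  if (kind == "relation")
    stop_validation("relations are stored with bg_upsert_relation()")
  id <- bg_id(object)
  if (node_present(db, id)) return(list(id = id, inserted = FALSE))
  txn$pending_nodes[[id]] <- list(kind = kind, object = object)
  list(id = id, inserted = TRUE)
}

#' Insert a relation, skipping duplicates
#'
#' Both endpoints must already be stored (committed or pending in the same
#' transaction), and the endpoint kinds must be legal for the label:
#' HAS_ID connects an entity to an identifier, HAS_DATA an entity to a
#' data object, and every other label connects entities.
#'
#' @param db A `bg_db`.
#' @param relation A `bg_relation`.
#' @return List with `id` and `inserted`.
#' @export
bg_upsert_relation <- function(db, relation) {
  txn <- txn_check_open(db)
  stopifnot(inherits(relation, "bg_relation"))
  src <- node_record(db, relation$source_id, pending_ok = TRUE)
  tgt <- node_record(db, relation$target_id, pending_ok = TRUE)
  if (is.null(src))
    stop("dangling source endpoint: ", substr(relation$source_id, 1, 12), call. = FALSE)
  if (is.null(tgt))
    stop("dangling target endpoint: ", substr(relation$target_id, 1, 12), call. = FALSE)
  ok <- switch(relation$label,
    HAS_ID = src$kind == "entity" && tgt$kind == "identifier",
    HAS_DATA = src$kind == "entity" && tgt$kind == "data",
    src$kind == "entity" && tgt$kind == "entity")
  if (!ok)
    stop_validation("relation %s may not connect a %s node to a %s node",
                    relation$label, src$kind, tgt$kind)
  id <- bg_id(relation)
  present <- exists(id, envir = db$edges, inherits = FALSE) ||
    !is.null(txn$pending_edges[[id]])
  if (present) return(list(id = id, inserted = FALSE))
  txn$pending_edges[[id]] <- relation
  list(id = id, inserted = TRUE)
}

#' Fetch a stored object by ID
#'
#' @param db A `bg_db`.
#' @param id ObjectID.
#' @return The stored model object (nodes) or relation (edges).
#' @export
bg_get <- function(db, id) {
  rec <- node_record(db, id)
  if (!is.null(rec)) return(rec$object)
  if (exists(id, envir = db$edges, inherits = FALSE))
    return(get(id, envir = db$edges, inherits = FALSE))
  stop("object not found: ", substr(id, 1, 12), call. = FALSE)
}

#' List incident relations and neighbor objects
#'
#' @param db A `bg_db`.
#' @param id ObjectID of a stored node.
#' @param label Optional relation-label filter (normalized).
#' @param direction "out", "in" or "any".
#' @return List of `list(relation=, relation_id=, neighbor=, neighbor_id=)`
#'   sorted by relation ID (deterministic).
#' @export
bg_neighbors <- function(db, id, label = NULL, direction = c("any", "out", "in")) {
  direction <- match.arg(direction)
  if (is.null(node_record(db, id)))
    stop("object not found: ", substr(id, 1, 12), call. = FALSE)
  if (!is.null(label)) label <- bg_normalize_label(label)
  eids <- character(0)
  if (direction %in% c("out", "any") && exists(id, envir = db$adj_out, inherits = FALSE))
    eids <- c(eids, get(id, envir = db$adj_out, inherits = FALSE))
  if (direction %in% c("in", "any") && exists(id, envir = db$adj_in, inherits = FALSE))
    eids <- c(eids, get(id, envir = db$adj_in, inherits = FALSE))
  eids <- sort(unique(eids), method = "radix")
  out <- list()
  for (eid in eids) {
    rel <- get(eid, envir = db$edges, inherits = FALSE)
    if (!is.null(label) && rel$label != label) next
    other <- if (rel$source_id == id) rel$target_id else rel$source_id
    out[[length(out) + 1L]] <- list(relation = rel, relation_id = eid,
                                    neighbor = bg_get(db, other),
                                    neighbor_id = other)
  }
  out
}

#' Database statistics
#'
#' @param db A `bg_db`.
#' @return List with counts of nodes by kind, total relations and
#'   relations by label; maintained counters, O(1).
#' @export
bg_stats <- function(db) {
  lbl <- db$edges_by_label
  if (length(lbl)) lbl <- lbl[order(names(lbl), method = "radix")]
  list(entities = db$counts$entity,
       identifiers = db$counts$identifier,
       data_objects = db$counts$data,
       nodes = db$counts$entity + db$counts$identifier + db$counts$data,
       relations = db$edge_count,
       relations_by_label = lbl)
}

#' All stored entity IDs, optionally of one type
#'
#' @param db A `bg_db`.
#' @param entity_type Optional lowercase type filter.
#' @return Sorted character vector of ObjectIDs.
#' @export
bg_entities <- function(db, entity_type = NULL) {
  ids <- ls(db$nodes, sorted = TRUE)
  keep <- vapply(ids, function(i) {
    rec <- get(i, envir = db$nodes, inherits = FALSE)
    rec$kind == "entity" &&
      (is.null(entity_type) || rec$object$entity_type == tolower(entity_type))
  }, logical(1))
  ids[keep]
}

#' All stored edge IDs
#' @param db A `bg_db`.
#' @return Sorted character vector of relation ObjectIDs.
#' @export
bg_edges <- function(db) ls(db$edges, sorted = TRUE)

#' Graph-database adapter stub
#'
#' The store above is the reference implementation of the adapter
#' contract (`upsert_node`, `upsert_edge`, `neighbors`, `stats`). This
#' stub documents the surface a server-backed graph database (e.g. a
#' Cypher-speaking one) would implement; calling any method signals
#' not-implemented.
#'
#' @param uri Server URI (unused).
#' @return An object whose methods all raise "not implemented".
#' @export
bg_neo4j_adapter <- function(uri = "bolt://localhost:7687") {
  unimplemented <- function(...) {
    stop("server-backed adapter not implemented; use the embedded store (bg_db)",
         call. = FALSE)
  }
  structure(list(uri = uri, upsert_node = unimplemented,
                 upsert_edge = unimplemented, neighbors = unimplemented,
                 stats = unimplemented),
            class = "bg_adapter_stub")
}
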