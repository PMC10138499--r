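#' @title Snapshots
#' @description
#' The embedded database persists as a JSON-lines snapshot: one record
#' per node, edge, catalog entry, index posting and import record, in a
#' documented deterministic order (nodes by ID, edges by ID, entries in
#' log order, postings by index then token, imports in log order). A
#' `.gz` extension selects gzip compression. Reading a snapshot
#' reconstructs an identical database: same IDs, same stats, same
#' keyword-search behavior.
#' @name snapshot
NULL

object_to_list <- function(kind, object) {
  switch(kind,
    entity = list(entity_type = object$entity_type,
                  primary_identifier = object$primary_identifier),
    identifier = list(id_type = object$id_type, title = object$title,
                      value = object$value),
    data = list(source_label = object$source_label, payload = object$payload),
    relation = list(label = object$label, source_id = object$source_id,
                    target_id = object$target_id, props = object$props))
}

object_from_list <- function(kind, x) {
  switch(kind,
    entity = bg_entity(x$entity_type, x$primary_identifier),
    identifier = bg_identifier(x$id_type, x$title, x$value),
    data = bg_data(x$source_label, x$payload),
    relation = bg_relation(x$label, x$source_id, x$target_id,
                           if (length(x$props)) x$props else list()))
}

snapshot_conn <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a database snapshot
#'
#' @param db A `bg_db`.
#' @param path Output path; gzip-compressed when it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
bg_snapshot_write <- function(db, path) {
  con <- snapshot_conn(path, "wb")
  on.exit(close(con))
  emit <- function(x) {
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), con,
               useBytes = TRUE)
  }
  emit(list(record = "header", format = "biograph-snapshot", version = 1L))
  for (id in ls(db$nodes, sorted = TRUE)) {
    rec <- get(id, envir = db$nodes, inherits = FALSE)
    emit(list(record = "node", kind = rec$kind,
              object = object_to_list(rec$kind, rec$object)))
  }
  for (id in ls(db$edges, sorted = TRUE)) {
    rel <- get(id, envir = db$edges, inherits = FALSE)
    emit(list(record = "edge", object = object_to_list("relation", rel)))
  }
  for (row in db$catalog$entries)
    emit(list(record = "entry", id = row$id, kind = row$kind,
              import_id = row$import_id))
  for (idx in c("identifier", "description")) {
    root <- if (idx == "identifier") db$catalog$id_trie else db$catalog$desc_trie
    for (p in trie_enumerate(root))
      emit(list(record = "posting", index = idx, token = p$token, ids = p$ids))
  }
  for (rec in db$catalog$imports)
    emit(list(record = "import", data = rec))
  emit(list(record = "footer", import_seq = db$catalog$import_seq))
  invisible(path)
}

#' Read a database snapshot
#'
#' @param path Snapshot path written by [bg_snapshot_write()].
#' @return A reconstructed `bg_db`.
#' @export
bg_snapshot_read <- function(path) {
  if (!file.exists(path)) stop("snapshot not found: ", path, call. = FALSE)
  con <- snapshot_conn(path, "rb")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L)
    stop("parse error at line 1: empty snapshot", call. = FALSE)
  parse_line <- function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e)
                      stop(sprintf("parse error at line %d: %s", i,
                                   conditionMessage(e)), call. = FALSE))
    if (!is.list(rec) || is.null(rec$record))
      stop(sprintf("parse error at line %d: missing 'record' field", i),
           call. = FALSE)
    rec
  }
  head <- parse_line(1L)
  if (!identical(head$record, "header") ||
      !identical(head$format, "biograph-snapshot"))
    stop("parse error at line 1: not a biograph snapshot", call. = FALSE)
  db <- bg_db()
  txn <- bg_begin(db)
  saw_footer <- FALSE
  for (i in seq_along(lines)[-1]) {
    rec <- parse_line(i)
    switch(rec$record,
      node = {
        obj <- object_from_list(rec$kind, rec$object)
        bg_upsert(db, obj)
      },
      edge = {
        rel <- object_from_list("relation", rec$object)
        bg_upsert_relation(db, rel)
      },
      entry = {
        txn$catalog$entries[[length(txn$catalog$entries) + 1L]] <-
          list(id = rec$id, kind = rec$kind, import_id = rec$import_id)
        assign(paste0(rec$id, "|", rec$import_id), TRUE,
               envir = txn$catalog$entry_seen)
      },
      posting = {
        txn$catalog$postings[[length(txn$catalog$postings) + 1L]] <-
          list(index = rec$index, token = rec$token,
               ids = unlist(rec$ids, use.names = FALSE))
      },
      import = {
        imp <- rec$data
        imp$object_ids <- unlist(imp$object_ids %||% list(), use.names = FALSE)
        imp$inserted <- as.integer(imp$inserted)
        imp$skipped <- as.integer(imp$skipped)
        r <- list2env(imp, parent = emptyenv())
        class(r) <- "bg_import_record"
        txn$catalog$imports[[length(txn$catalog$imports) + 1L]] <- r
      },
      footer = {
        saw_footer <- TRUE
        txn$catalog$import_seq_delta <- as.integer(rec$import_seq)
      },
      stop(sprintf("parse error at line %d: unknown record type '%s'",
                   i, rec$record), call. = FALSE)
    )
  }
  if (!saw_footer)
    stop(sprintf("parse error at line %d: truncated snapshot (no footer)",
                 length(lines)), call. = FALSE)
  bg_commit(txn)
  db
}

`%||%` <- function(a, b) if (is.null(a)) b else a
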