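#' @title Catalog index
#' @description
#' Alongside the graph, a catalog database records every stored object
#' (entry indexer), every import (import indexer), and keyword-searchable
#' text: identifier values (identifier indexer) and free-text
#' descriptions (description indexer). Text is held in prefix trees so
#' exact and prefix keyword queries run without scanning. Catalog writes
#' ride the same transaction as graph writes, keeping both synchronized.
#' @name catalog
NULL

# ---- prefix tree -----------------------------------------------------------

trie_new <- function() {
  node <- new.env(parent = emptyenv())
  node$children <- new.env(parent = emptyenv())
  node$postings <- character(0)
  node
}

trie_insert <- function(root, token, ids) {
  node <- root
  for (ch in strsplit(token, "", fixed = TRUE)[[1]]) {
    child <- if (exists(ch, envir = node$children, inherits = FALSE))
      get(ch, envir = node$children, inherits = FALSE) else NULL
    if (is.null(child)) {
      child <- trie_new()
      assign(ch, child, envir = node$children)
    }
    node <- child
  }
  node$postings <- sort(unique(c(node$postings, ids)), method = "radix")
  invisible(root)
}

trie_walk <- function(root, token) {
  node <- root
  for (ch in strsplit(token, "", fixed = TRUE)[[1]]) {
    if (!exists(ch, envir = node$children, inherits = FALSE)) return(NULL)
    node <- get(ch, envir = node$children, inherits = FALSE)
  }
  node
}

trie_lookup <- function(root, token) {
  node <- trie_walk(root, token)
  if (is.null(node)) character(0) else node$postings
}

trie_collect <- function(node) {
  out <- node$postings
  for (ch in ls(node$children, sorted = TRUE))
    out <- c(out, trie_collect(get(ch, envir = node$children, inherits = FALSE)))
  out
}

trie_prefix <- function(root, prefix) {
  node <- trie_walk(root, prefix)
  if (is.null(node)) character(0)
  else sort(unique(trie_collect(node)), method = "radix")
}

# enumerate (token, postings) pairs, tokens in lexicographic order
trie_enumerate <- function(node, prefix = "") {
  out <- list()
  if (length(node$postings))
    out[[length(out) + 1L]] <- list(token = prefix, ids = node$postings)
  for (ch in ls(node$children, sorted = TRUE))
    out <- c(out, trie_enumerate(get(ch, envir = node$children, inherits = FALSE),
                                 paste0(prefix, ch)))
  out
}

# ---- catalog state ---------------------------------------------------------

bg_catalog_new <- function() {
  cat_ <- new.env(parent = emptyenv())
  cat_$entries <- list()              # list(id, kind, import_id)
  cat_$entry_seen <- new.env(parent = emptyenv())
  cat_$id_trie <- trie_new()
  cat_$desc_trie <- trie_new()
  cat_$imports <- list()              # import_id -> finished record (list)
  cat_$import_seq <- 0L
  cat_
}

bg_catalog_pending <- function() {
  p <- new.env(parent = emptyenv())
  p$entries <- list()
  p$entry_seen <- new.env(parent = emptyenv())
  p$postings <- list()                # list(index, token, ids)
  p$imports <- list()                 # import record envs
  p$import_seq_delta <- 0L
  p
}

bg_catalog_apply <- function(cat_, pending) {
  for (row in pending$entries) {
    cat_$entries[[length(cat_$entries) + 1L]] <- row
    assign(paste0(row$id, "|", row$import_id), TRUE, envir = cat_$entry_seen)
  }
  for (p in pending$postings) {
    root <- if (p$index == "identifier") cat_$id_trie else cat_$desc_trie
    trie_insert(root, p$token, p$ids)
  }
  for (rec in pending$imports)
    cat_$imports[[rec$import_id]] <- mget(
      c("import_id", "source_label", "started", "finished",
        "inserted", "skipped", "object_ids", "state"), envir = rec)
  cat_$import_seq <- cat_$import_seq + pending$import_seq_delta
  invisible(cat_)
}

# ---- tokenization ----------------------------------------------------------

#' Tokenize text for keyword indexing
#'
#' Lowercases, splits on any non-alphanumeric run, and keeps tokens of at
#' least two characters. Indexing is therefore invariant to case and to
#' leading/trailing whitespace.
#'
#' @param text Character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
bg_tokenize <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nchar(toks) >= 2L]
}

# ---- indexers --------------------------------------------------------------

#' Log an object or relation in the entry index
#'
#' One log row per (ID, import); replaying the same ID within the same
#' import logs nothing new.
#'
#' @param db A `bg_db` with an open transaction.
#' @param id ObjectID of the stored object or relation.
#' @param kind "entity", "identifier", "data" or "relation".
#' @param import_id Import this entry belongs to.
#' @export
bg_index_entry <- function(db, id, kind, import_id) {
  txn <- txn_check_open(db)
  key <- paste0(id, "|", import_id)
  if (exists(key, envir = db$catalog$entry_seen, inherits = FALSE) ||
      exists(key, envir = txn$catalog$entry_seen, inherits = FALSE))
    return(invisible(FALSE))
  txn$catalog$entries[[length(txn$catalog$entries) + 1L]] <-
    list(id = id, kind = kind, import_id = import_id)
  assign(key, TRUE, envir = txn$catalog$entry_seen)
  invisible(TRUE)
}

#' Index an identifier's value for keyword lookup
#'
#' The identifier value is tokenized and each token — plus the full
#' lowercased value verbatim, so exact ID lookup always works — is
#' inserted into the identifier prefix tree with the owning entities as
#' postings.
#'
#' @param db A `bg_db` with an open transaction.
#' @param identifier A `bg_identifier`.
#' @param entity_ids Nonempty character vector of owning entity ObjectIDs.
#' @export
bg_index_identifier <- function(db, identifier, entity_ids) {
  txn <- txn_check_open(db)
  stopifnot(inherits(identifier, "bg_identifier"), length(entity_ids) > 0L)
  verbatim <- tolower(bg_trim(identifier$value))
  toks <- unique(c(bg_tokenize(identifier$value), verbatim))
  for (tok in toks)
    txn$catalog$postings[[length(txn$catalog$postings) + 1L]] <-
      list(index = "identifier", token = tok, ids = entity_ids)
  invisible(TRUE)
}

#' Index a text description of an object
#'
#' @param db A `bg_db` with an open transaction.
#' @param object_id ObjectID the description belongs to.
#' @param text Nonempty description text; tokenized words go into the
#'   description prefix tree. Punctuation-only text indexes nothing.
#' @export
bg_index_description <- function(db, object_id, text) {
  txn <- txn_check_open(db)
  check_nonempty(text, "text")
  for (tok in unique(bg_tokenize(text)))
    txn$catalog$postings[[length(txn$catalog$postings) + 1L]] <-
      list(index = "description", token = tok, ids = object_id)
  invisible(TRUE)
}

#' Keyword search over identifier and description indexes
#'
#' Case-insensitive token match — exact or prefix — executed on the
#' catalog's prefix trees; the union of postings is optionally filtered
#' by entity type.
#'
#' @param db A `bg_db`.
#' @param term Nonempty search term.
#' @param entity_type Optional type filter ("disease", "gene", ...).
#' @param mode "exact" or "prefix".
#' @return Sorted character vector of matching ObjectIDs.
#' @examples
#' \dontrun{bg_keyword_search(db, "pneumonia", entity_type = "disease")}
#' @export
bg_keyword_search <- function(db, term, entity_type = NULL,
                              mode = c("exact", "prefix")) {
  mode <- match.arg(mode)
  term <- tolower(bg_trim(term))
  if (!nzchar(term)) stop_validation("search term must be nonempty")
  cat_ <- db$catalog
  hits <- if (mode == "exact")
    c(trie_lookup(cat_$id_trie, term), trie_lookup(cat_$desc_trie, term))
  else
    c(trie_prefix(cat_$id_trie, term), trie_prefix(cat_$desc_trie, term))
  hits <- sort(unique(hits), method = "radix")
  if (!is.null(entity_type)) {
    entity_type <- tolower(entity_type)
    keep <- vapply(hits, function(i) {
      rec <- node_record(db, i)
      !is.null(rec) && rec$kind == "entity" &&
        rec$object$entity_type == entity_type
    }, logical(1))
    hits <- hits[keep]
  }
  hits
}

#' Catalog entry rows
#'
#' @param db A `bg_db`.
#' @param import_id Optional filter.
#' @return data.frame with columns id, kind, import_id.
#' @export
bg_entries <- function(db, import_id = NULL) {
  rows <- db$catalog$entries
  if (!is.null(import_id))
    rows <- Filter(function(r) r$import_id == import_id, rows)
  if (length(rows) == 0L)
    return(data.frame(id = character(0), kind = character(0),
                      import_id = character(0), stringsAsFactors = FALSE))
  data.frame(id = vapply(rows, `[[`, "", "id"),
             kind = vapply(rows, `[[`, "", "kind"),
             import_id = vapply(rows, `[[`, "", "import_id"),
             stringsAsFactors = FALSE)
}

# ---- import log ------------------------------------------------------------

#' Open an import record
#'
#' The import indexer logs every import: its source, start/finish times,
#' how many submitted objects were inserted vs skipped as duplicates, and
#' which object IDs were touched. The record is persisted at commit.
#'
#' @param db A `bg_db` with an open transaction.
#' @param source_label Dataset source label.
#' @return An open import record (mutable handle).
#' @export
bg_log_import <- function(db, source_label) {
  txn <- txn_check_open(db)
  check_nonempty(source_label, "source_label")
  txn$catalog$import_seq_delta <- txn$catalog$import_seq_delta + 1L
  seq_no <- db$catalog$import_seq + txn$catalog$import_seq_delta
  rec <- new.env(parent = emptyenv())
  rec$import_id <- sprintf("imp%06d", seq_no)
  rec$source_label <- source_label
  rec$started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
  rec$finished <- NA_character_
  rec$inserted <- 0L
  rec$skipped <- 0L
  rec$object_ids <- character(0)
  rec$state <- "open"
  class(rec) <- "bg_import_record"
  txn$catalog$imports[[length(txn$catalog$imports) + 1L]] <- rec
  rec
}

#' Close an import record with its counts
#'
#' @param record Open record from [bg_log_import()].
#' @param inserted,skipped Object/relation counts; their sum must equal
#'   the number of submitted objects.
#' @return The finished record, invisibly.
#' @export
bg_finish_import <- function(record, inserted, skipped) {
  stopifnot(inherits(record, "bg_import_record"))
  if (record$state != "open") stop("import record already finished", call. = FALSE)
  record$inserted <- as.integer(inserted)
  record$skipped <- as.integer(skipped)
  record$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
  record$state <- "finished"
  invisible(record)
}

#' List committed import records
#'
#' @param db A `bg_db`.
#' @return List of import records in log order.
#' @export
bg_imports <- function(db) unname(db$catalog$imports)

#' @export
print.bg_import_record <- function(x, ...) {
  cat(sprintf("<import %s source=%s inserted=%d skipped=%d %s>\n",
              x$import_id, x$source_label, x$inserted, x$skipped, x$state))
  invisible(x)
}
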