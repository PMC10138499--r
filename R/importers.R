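#' @title Importer framework and dataset dialects
#' @description
#' Importers turn dataset files into model objects through a small core
#' contract of five essential methods: `begin_import(source_label)`,
#' `map_entity`, `map_identifier` / `map_data` (object mapping),
#' `map_relation`, and `finish_import()`. Every mapped object is content
#' addressed, deduplicated against the store, catalog-indexed and written
#' inside one transaction, so imports are idempotent and atomic: an
#' aborted import leaves graph and catalog untouched. Five dialect
#' importers are provided, one per supported dataset shape (DisProt,
#' HGNC, DisGeNET, IEDB, Tantigen styles); each reads its field names
#' from a small mapping config (shipped defaults under
#' `inst/extdata/mappings/`) since column names vary between releases.
#' @name importers
NULL

#' Open an import contract on a database
#'
#' @param db A `bg_db`.
#' @return A list of the contract methods described above. `map_*`
#'   methods return `list(id, inserted)`; `finish_import()` commits and
#'   returns the finished import record; `abort_import()` rolls back.
#' @export
bg_import_contract <- function(db) {
  state <- new.env(parent = emptyenv())
  state$txn <- NULL
  state$record <- NULL
  state$inserted <- 0L
  state$skipped <- 0L
  state$ids <- character(0)

  tally <- function(res, kind) {
    if (res$inserted) state$inserted <- state$inserted + 1L
    else state$skipped <- state$skipped + 1L
    state$ids <- unique(c(state$ids, res$id))
    bg_index_entry(db, res$id, kind, state$record$import_id)
    res
  }
  need_open <- function() {
    if (is.null(state$record)) stop("call begin_import() first", call. = FALSE)
  }

  begin_import <- function(source_label) {
    if (!is.null(state$record)) stop("import already begun", call. = FALSE)
    state$txn <- bg_begin(db)
    state$record <- bg_log_import(db, source_label)
    invisible(state$record$import_id)
  }
  map_entity <- function(entity, description = NULL) {
    need_open()
    res <- tally(bg_upsert(db, entity), "entity")
    if (!is.null(description) && nzchar(bg_trim(description)))
      bg_index_description(db, res$id, description)
    res
  }
  map_identifier <- function(identifier, owner_entity) {
    need_open()
    owner_id <- bg_id(owner_entity)
    res <- tally(bg_upsert(db, identifier), "identifier")
    rel <- bg_relation("HAS_ID", owner_id, res$id)
    tally(bg_upsert_relation(db, rel), "relation")
    bg_index_identifier(db, identifier, owner_id)
    res
  }
  map_data <- function(data, owner_entity) {
    need_open()
    owner_id <- bg_id(owner_entity)
    res <- tally(bg_upsert(db, data), "data")
    rel <- bg_relation("HAS_DATA", owner_id, res$id)
    tally(bg_upsert_relation(db, rel), "relation")
    res
  }
  map_relation <- function(label, source_entity, target_entity, props = list()) {
    need_open()
    rel <- bg_relation(label, bg_id(source_entity), bg_id(target_entity), props)
    tally(bg_upsert_relation(db, rel), "relation")
  }
  finish_import <- function() {
    need_open()
    rec <- state$record
    rec$object_ids <- state$ids
    bg_finish_import(rec, state$inserted, state$skipped)
    bg_commit(state$txn)
    state$record <- NULL
    state$txn <- NULL
    rec
  }
  abort_import <- function() {
    if (!is.null(state$txn) && state$txn$state == "open") bg_rollback(state$txn)
    state$record <- NULL
    state$txn <- NULL
    invisible(NULL)
  }
  list(begin_import = begin_import, map_entity = map_entity,
       map_identifier = map_identifier, map_data = map_data,
       map_relation = map_relation, finish_import = finish_import,
       abort_import = abort_import)
}

#' Default mapping config for a dialect
#'
#' @param dialect One of "disprot", "hgnc", "disgenet", "iedb", "tantigen".
#' @return Named list of field names used by the dialect's importer.
#' @export
bg_mapping_config <- function(dialect) {
  path <- system.file("extdata", "mappings", paste0(dialect, ".json"),
                      package = "biograph")
  if (!nzchar(path)) stop_validation("no mapping config for dialect '%s'", dialect)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

read_tsv_records <- function(path, required, config_name) {
  if (!file.exists(path)) stop("input not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE, quote = "", comment.char = ""),
    error = function(e) stop("structural failure reading ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  missing <- setdiff(unlist(required), names(df))
  if (length(missing))
    stop(sprintf("missing required column(s) %s in %s (per %s mapping config)",
                 paste(missing, collapse = ", "), path, config_name),
         call. = FALSE)
  df
}

read_json_records <- function(path) {
  if (!file.exists(path)) stop("input not found: ", path, call. = FALSE)
  recs <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                   error = function(e) stop("structural failure reading ", path,
                                            ": ", conditionMessage(e),
                                            call. = FALSE))
  if (!is.list(recs)) stop("structural failure: expected a JSON array in ",
                           path, call. = FALSE)
  recs
}

field <- function(rec, name) {
  if (is.null(name)) return(NULL)
  v <- rec[[name]]
  if (is.null(v) || length(v) != 1L || is.na(v) || !nzchar(bg_trim(as.character(v))))
    NULL
  else v
}

run_import <- function(db, source_label, body) {
  contract <- bg_import_contract(db)
  contract$begin_import(source_label)
  res <- tryCatch(body(contract), error = function(e) e)
  if (inherits(res, "error")) {
    contract$abort_import()
    stop(res)
  }
  rec <- contract$finish_import()
  rec$records_read <- res$read
  rec$records_skipped <- res$rows_skipped
  rec
}

#' Import a DisGeNET-style gene–disease TSV
#'
#' Each row yields a gene entity (primary identifier = gene symbol), a
#' disease entity (primary identifier = the disease CUI), a RELATED_WITH
#' relation gene → disease carrying the association score, a disease CUI
#' identifier object, and extra columns (e.g. the disease name) as a data
#' object with source label "disgenet". The disease name is also indexed
#' as a description for keyword search. A missing required column aborts
#' the whole import (rollback); a row with an unparsable score is skipped
#' with a warning.
#'
#' @param db A `bg_db`.
#' @param path TSV file with a header row.
#' @param config Mapping config (defaults shipped with the package).
#' @return The finished import record.
#' @export
bg_import_disgenet <- function(db, path, config = bg_mapping_config("disgenet")) {
  df <- read_tsv_records(path, config[c("gene_col", "disease_col", "score_col")],
                         "disgenet")
  run_import(db, "disgenet", function(ct) {
    rows_skipped <- 0L
    for (i in seq_len(nrow(df))) {
      gene_sym <- field(df[i, ], config$gene_col)
      cui <- field(df[i, ], config$disease_col)
      score <- suppressWarnings(as.numeric(df[i, ][[config$score_col]]))
      if (is.null(gene_sym) || is.null(cui) || is.na(score)) {
        warning(sprintf("disgenet row %d skipped (missing field or unparsable score)", i),
                call. = FALSE)
        rows_skipped <- rows_skipped + 1L
        next
      }
      gene <- bg_entity("gene", gene_sym)
      disease <- bg_entity("disease", cui)
      disease_name <- field(df[i, ], config$disease_name_col)
      ct$map_entity(gene)
      ct$map_entity(disease, description = disease_name)
      ct$map_identifier(bg_identifier("id", "UMLS CUI", cui), disease)
      if (!is.null(disease_name))
        ct$map_data(bg_data("disgenet", list(disease_name = disease_name)),
                    disease)
      ct$map_relation("RELATED_WITH", gene, disease, list(score = score))
    }
    list(read = nrow(df), rows_skipped = rows_skipped)
  })
}

#' Import an HGNC-style gene JSON file
#'
#' Each record yields a gene entity (primary identifier = gene symbol)
#' with a gene-name identifier, an NCBI ID identifier when present, the
#' chromosome location as a data object with source label "hgnc", and —
#' when the record carries a protein (UniProt) reference — a protein
#' entity linked by a FROM relation protein → gene. Records without a
#' gene symbol are skipped with a warning.
#'
#' @inheritParams bg_import_disgenet
#' @return The finished import record.
#' @export
bg_import_hgnc <- function(db, path, config = bg_mapping_config("hgnc")) {
  recs <- read_json_records(path)
  run_import(db, "hgnc", function(ct) {
    rows_skipped <- 0L
    for (i in seq_along(recs)) {
      rec <- recs[[i]]
      sym <- field(rec, config$symbol_field)
      if (is.null(sym)) {
        warning(sprintf("hgnc record %d skipped (no gene symbol)", i), call. = FALSE)
        rows_skipped <- rows_skipped + 1L
        next
      }
      gene <- bg_entity("gene", sym)
      ct$map_entity(gene)
      ct$map_identifier(bg_identifier("name", "gene name", sym), gene)
      ncbi <- field(rec, config$ncbi_field)
      if (!is.null(ncbi))
        ct$map_identifier(bg_identifier("id", "NCBI ID", as.character(ncbi)), gene)
      loc <- field(rec, config$location_field)
      if (!is.null(loc))
        ct$map_data(bg_data("hgnc", list(location = loc)), gene)
      uniprot <- field(rec, config$uniprot_field)
      if (!is.null(uniprot)) {
        protein <- bg_entity("protein", uniprot)
        ct$map_entity(protein)
        ct$map_relation("FROM", protein, gene)
      }
    }
    list(read = length(recs), rows_skipped = rows_skipped)
  })
}

#' Import a DisProt-style disordered-protein JSON file
#'
#' Each record yields a protein entity (primary identifier = UniProt
#' accession), UniProt and DisProt identifier objects, and the disorder
#' content — the fraction of the protein annotated as intrinsically
#' disordered — as a data object with source label "disprot". A disorder
#' content outside \[0, 1\] is stored as-is with a warning. When the
#' record names an organism taxon, an organism entity is created and
#' linked by FROM protein → organism. Records without an accession are
#' skipped with a warning.
#'
#' @inheritParams bg_import_disgenet
#' @return The finished import record.
#' @export
bg_import_disprot <- function(db, path, config = bg_mapping_config("disprot")) {
  recs <- read_json_records(path)
  run_import(db, "disprot", function(ct) {
    rows_skipped <- 0L
    for (i in seq_along(recs)) {
      rec <- recs[[i]]
      acc <- field(rec, config$accession_field)
      if (is.null(acc)) {
        warning(sprintf("disprot record %d skipped (no UniProt accession)", i),
                call. = FALSE)
        rows_skipped <- rows_skipped + 1L
        next
      }
      protein <- bg_entity("protein", acc)
      ct$map_entity(protein)
      ct$map_identifier(bg_identifier("id", "UniProt ID", acc), protein)
      dpid <- field(rec, config$disprot_id_field)
      if (!is.null(dpid))
        ct$map_identifier(bg_identifier("id", "DisProt ID", dpid), protein)
      dc <- field(rec, config$disorder_field)
      if (!is.null(dc)) {
        dc <- as.numeric(dc)
        if (!is.na(dc)) {
          if (dc < 0 || dc > 1)
            warning(sprintf("disprot record %d: disorder content %g outside [0,1], stored as-is",
                            i, dc), call. = FALSE)
          ct$map_data(bg_data("disprot", list(disorder_content = dc)), protein)
        }
      }
      taxon <- field(rec, config$taxon_field)
      if (!is.null(taxon)) {
        organism <- bg_entity("organism", as.character(taxon))
        ct$map_entity(organism)
        ct$map_relation("FROM", protein, organism)
      }
    }
    list(read = length(recs), rows_skipped = rows_skipped)
  })
}

#' Import a Tantigen-style tumor-antigen JSON file
#'
#' Each record yields an antigen entity (primary identifier = antigen
#' accession) with its accession identifier, the antigen full name as a
#' data object (source label "tantigen") indexed as a description,
#' epitope entities (primary identifier = amino-acid sequence) linked by
#' CONTAINS antigen → epitope, and — when the antigen names its gene — a
#' gene entity linked by IS gene → antigen.
#'
#' @inheritParams bg_import_disgenet
#' @return The finished import record.
#' @export
bg_import_tantigen <- function(db, path, config = bg_mapping_config("tantigen")) {
  recs <- read_json_records(path)
  run_import(db, "tantigen", function(ct) {
    rows_skipped <- 0L
    for (i in seq_along(recs)) {
      rec <- recs[[i]]
      acc <- field(rec, config$accession_field)
      if (is.null(acc)) {
        warning(sprintf("tantigen record %d skipped (no accession)", i), call. = FALSE)
        rows_skipped <- rows_skipped + 1L
        next
      }
      antigen <- bg_entity("antigen", acc)
      full_name <- field(rec, config$name_field)
      ct$map_entity(antigen, description = full_name)
      ct$map_identifier(bg_identifier("id", "Tantigen ID", acc), antigen)
      if (!is.null(full_name))
        ct$map_data(bg_data("tantigen", list(full_name = full_name)), antigen)
      gene_sym <- field(rec, config$gene_field)
      if (!is.null(gene_sym)) {
        gene <- bg_entity("gene", gene_sym)
        ct$map_entity(gene)
        ct$map_relation("IS", gene, antigen)
      }
      for (seq_ in rec[[config$epitopes_field]] %||% list()) {
        if (is.null(seq_) || !nzchar(bg_trim(as.character(seq_)))) next
        epitope <- bg_entity("epitope", seq_)
        ct$map_entity(epitope)
        ct$map_relation("CONTAINS", antigen, epitope)
      }
    }
    list(read = length(recs), rows_skipped = rows_skipped)
  })
}

#' Import an IEDB-style epitope TSV
#'
#' Each row yields an epitope entity (primary identifier = sequence),
#' its type annotation as a data object (source label "iedb"), an
#' antigen entity linked by CONTAINS antigen → epitope, and — when an
#' organism taxon is present — an organism entity linked by FROM
#' epitope → organism. Rows without an epitope sequence are skipped with
#' a warning.
#'
#' @inheritParams bg_import_disgenet
#' @return The finished import record.
#' @export
bg_import_iedb <- function(db, path, config = bg_mapping_config("iedb")) {
  df <- read_tsv_records(path, config[c("epitope_col", "antigen_col")], "iedb")
  run_import(db, "iedb", function(ct) {
    rows_skipped <- 0L
    for (i in seq_len(nrow(df))) {
      seq_ <- field(df[i, ], config$epitope_col)
      antigen_id <- field(df[i, ], config$antigen_col)
      if (is.null(seq_) || is.null(antigen_id)) {
        warning(sprintf("iedb row %d skipped (missing epitope or antigen)", i),
                call. = FALSE)
        rows_skipped <- rows_skipped + 1L
        next
      }
      epitope <- bg_entity("epitope", seq_)
      ct$map_entity(epitope)
      etype <- field(df[i, ], config$type_col)
      if (!is.null(etype))
        ct$map_data(bg_data("iedb", list(epitope_type = etype)), epitope)
      antigen <- bg_entity("antigen", antigen_id)
      ct$map_entity(antigen)
      ct$map_relation("CONTAINS", antigen, epitope)
      taxon <- field(df[i, ], config$taxon_col)
      if (!is.null(taxon)) {
        organism <- bg_entity("organism", as.character(taxon))
        ct$map_entity(organism)
        ct$map_relation("FROM", epitope, organism)
      }
    }
    list(read = nrow(df), rows_skipped = rows_skipped)
  })
}

#' Dispatch an importer by name
#'
#' @param db A `bg_db`.
#' @param importer One of "disgenet", "hgnc", "disprot", "tantigen", "iedb".
#' @param path Input file.
#' @return The finished import record.
#' @export
bg_import <- function(db, importer, path) {
  fn <- switch(importer,
               disgenet = bg_import_disgenet, hgnc = bg_import_hgnc,
               disprot = bg_import_disprot, tantigen = bg_import_tantigen,
               iedb = bg_import_iedb,
               stop_validation("unknown importer '%s'; available: disgenet, hgnc, disprot, tantigen, iedb",
                               importer))
  fn(db, path)
}
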