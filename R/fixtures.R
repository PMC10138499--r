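#' @title Fixture generator
#' @description
#' The importers are exercised without downloads through a deterministic
#' generator that writes syntactically valid files in each of the five
#' dataset dialects. The special dialect `"worked_example"` reconstructs,
#' exactly and without randomness, the five-source example network: gene
#' CDKN1A (HGNC style, with NCBI identifier and chromosome location
#' 6p21.2), protein P38936 with DisProt identifier DP00016 and disorder
#' content 0.9 (DisProt style), disease C0038356 related to the gene with
#' association score 0.9 (DisGeNET style), tumor antigen Ag002102 with
#' epitope FAWERVRGL (Tantigen and IEDB styles). Randomized dialects draw
#' entity names from shared pools so the same genes, proteins, antigens
#' and epitopes recur across dialect files and cross-dataset joins are
#' exercised; the overlap rate is configurable through the pool size.
#' @name fixtures
NULL

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

fixture_pools <- function(n, seed, overlap) {
  # shared pools: smaller pools (higher overlap) make cross-dialect reuse
  # of the same entities more likely
  pool_size <- max(4L, ceiling(n / max(overlap, 0.05)) %/% 4L)
  epitopes <- with_seed(seed * 13L + 7L, {
    vapply(seq_len(pool_size), function(i)
      paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                     "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                   9, replace = TRUE), collapse = ""), character(1))
  })
  list(genes = sprintf("GENE%03d", seq_len(pool_size)),
       proteins = sprintf("P%05d", 10000L + seq_len(pool_size)),
       diseases = sprintf("C%07d", 100000L + seq_len(pool_size)),
       antigens = sprintf("Ag%06d", 500L + seq_len(pool_size)),
       epitopes = unique(epitopes))
}

DISEASE_NAMES <- c("Bacterial Pneumonia, Acute", "Stomach Neoplasms",
                   "Mammary Carcinoma", "Liver Cirrhosis", "Melanoma",
                   "Colorectal Neoplasms", "Diabetes Mellitus",
                   "Rheumatoid Arthritis", "Asthma", "Glioblastoma")

write_json_fixture <- function(records, path) {
  writeLines(jsonlite::toJSON(records, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path, useBytes = TRUE)
  path
}

write_tsv_fixture <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, useBytes = TRUE)
  for (i in seq_len(nrow(df)))
    writeLines(paste(vapply(df[i, ], as.character, ""), collapse = "\t"),
               con, useBytes = TRUE)
  path
}

worked_example_files <- function(out_dir) {
  paths <- c(
    hgnc = file.path(out_dir, "hgnc.json"),
    disprot = file.path(out_dir, "disprot.json"),
    disgenet = file.path(out_dir, "disgenet.tsv"),
    tantigen = file.path(out_dir, "tantigen.json"),
    iedb = file.path(out_dir, "iedb.tsv"))
  write_json_fixture(list(list(symbol = "CDKN1A", ncbi_id = "1026",
                               location = "6p21.2", uniprot = "P38936")),
                     paths[["hgnc"]])
  write_json_fixture(list(list(acc = "P38936", disprot_id = "DP00016",
                               disorder_content = 0.9)),
                     paths[["disprot"]])
  write_tsv_fixture(data.frame(gene_symbol = "CDKN1A",
                               disease_id = "C0038356",
                               disease_name = "Stomach Neoplasms",
                               score = "0.9", stringsAsFactors = FALSE),
                    paths[["disgenet"]])
  write_json_fixture(list(list(accession = "Ag002102",
                               full_name = "Cyclin-dependent kinase inhibitor 1",
                               gene = "CDKN1A",
                               epitopes = list("FAWERVRGL"))),
                     paths[["tantigen"]])
  write_tsv_fixture(data.frame(epitope_seq = "FAWERVRGL",
                               epitope_type = "T cell",
                               antigen_id = "Ag002102",
                               organism_taxon = "", stringsAsFactors = FALSE),
                    paths[["iedb"]])
  paths
}

#' Generate dataset fixture files
#'
#' @param dialect One of "disprot", "hgnc", "disgenet", "iedb",
#'   "tantigen" or "worked_example" (which ignores `n` and writes all
#'   five files of the deterministic example network).
#' @param n Number of records (randomized dialects).
#' @param seed Integer seed; the same seed always yields byte-identical
#'   files.
#' @param out_dir Output directory (created if needed).
#' @param overlap Cross-dialect entity-overlap rate in (0, 1]; higher
#'   values shrink the shared name pools so more entities recur across
#'   dialect files.
#' @return Named character vector of the written file paths.
#' @export
bg_generate_fixture <- function(dialect, n = 25L, seed = 1L, out_dir,
                                overlap = 0.3) {
  allowed <- c("disprot", "hgnc", "disgenet", "iedb", "tantigen",
               "worked_example")
  if (!dialect %in% allowed)
    stop_validation("unknown dialect '%s'; allowed: %s", dialect,
                    paste(allowed, collapse = ", "))
  stopifnot(n >= 0L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (dialect == "worked_example") return(worked_example_files(out_dir))

  pools <- fixture_pools(n, seed, overlap)
  with_seed(seed, switch(dialect,
    disgenet = {
      df <- data.frame(
        gene_symbol = sample(pools$genes, n, replace = TRUE),
        disease_id = sample(pools$diseases, n, replace = TRUE),
        disease_name = sample(DISEASE_NAMES, n, replace = TRUE),
        score = sprintf("%.3f", stats::runif(n)),
        stringsAsFactors = FALSE)
      c(disgenet = write_tsv_fixture(df, file.path(out_dir, "disgenet.tsv")))
    },
    hgnc = {
      syms <- sample(pools$genes, min(n, length(pools$genes)))
      recs <- lapply(seq_along(syms), function(i) {
        rec <- list(symbol = syms[[i]],
                    ncbi_id = as.character(sample.int(99999L, 1L)),
                    location = sprintf("%dp%d.%d", sample.int(22L, 1L),
                                       sample.int(25L, 1L), sample.int(3L, 1L)))
        if (stats::runif(1) < 0.8)
          rec$uniprot <- sample(pools$proteins, 1L)
        rec
      })
      c(hgnc = write_json_fixture(recs, file.path(out_dir, "hgnc.json")))
    },
    disprot = {
      accs <- sample(pools$proteins, min(n, length(pools$proteins)))
      recs <- lapply(seq_along(accs), function(i) {
        rec <- list(acc = accs[[i]],
                    disprot_id = sprintf("DP%05d", sample.int(99999L, 1L)),
                    disorder_content = round(stats::runif(1), 2))
        if (stats::runif(1) < 0.5) rec$taxon <- "9606"
        rec
      })
      c(disprot = write_json_fixture(recs, file.path(out_dir, "disprot.json")))
    },
    tantigen = {
      accs <- sample(pools$antigens, min(n, length(pools$antigens)))
      recs <- lapply(seq_along(accs), function(i) {
        rec <- list(accession = accs[[i]],
                    full_name = paste("Tumor antigen", accs[[i]]))
        if (stats::runif(1) < 0.7) rec$gene <- sample(pools$genes, 1L)
        rec$epitopes <- as.list(sample(pools$epitopes,
                                       sample.int(min(3L, length(pools$epitopes)), 1L)))
        rec
      })
      c(tantigen = write_json_fixture(recs, file.path(out_dir, "tantigen.json")))
    },
    iedb = {
      df <- data.frame(
        epitope_seq = sample(pools$epitopes, n, replace = TRUE),
        epitope_type = sample(c("T cell", "B cell"), n, replace = TRUE),
        antigen_id = sample(pools$antigens, n, replace = TRUE),
        organism_taxon = ifelse(stats::runif(n) < 0.5, "9606", ""),
        stringsAsFactors = FALSE)
      c(iedb = write_tsv_fixture(df, file.path(out_dir, "iedb.tsv")))
    }
  ))
}

#' Import the worked-example network into a database
#'
#' Generates the worked-example fixture files and imports all five,
#' yielding the example network of 5 entities (gene CDKN1A, protein
#' P38936, disease C0038356, antigen Ag002102, epitope FAWERVRGL) and 6
#' identifier objects, with content addressing joining the records that
#' different dialects contribute about the same entities.
#'
#' @param db A `bg_db` (default: a fresh one).
#' @param dir Directory for the fixture files (default: a temp dir).
#' @return The database, invisibly.
#' @export
bg_build_worked_example <- function(db = bg_db(), dir = tempfile("bgwe")) {
  paths <- bg_generate_fixture("worked_example", out_dir = dir)
  bg_import_hgnc(db, paths[["hgnc"]])
  bg_import_disprot(db, paths[["disprot"]])
  bg_import_disgenet(db, paths[["disgenet"]])
  bg_import_tantigen(db, paths[["tantigen"]])
  bg_import_iedb(db, paths[["iedb"]])
  invisible(db)
}

#' The example cross-dataset pattern query
#'
#' The query that reproduces the worked example end-to-end: diseases
#' RELATED_WITH genes at association score ≥ 0.5, where the gene's
#' protein (FROM protein → gene) has disorder content ≥ 0.9, the gene IS
#' a tumor antigen, and the antigen CONTAINS an epitope.
#'
#' @return A `bg_query`.
#' @export
bg_example_query <- function() {
  bg_parse_query(list(
    match = list(
      nodes = list(d = "disease", g = "gene", p = "protein",
                   a = "antigen", e = "epitope"),
      relations = list(
        list(from = "g", label = "RELATED_WITH", to = "d",
             direction = "out", alias = "rd"),
        list(from = "p", label = "FROM", to = "g", direction = "out"),
        list(from = "g", label = "IS", to = "a", direction = "out"),
        list(from = "a", label = "CONTAINS", to = "e", direction = "out"))),
    params = list(
      rd = list(list(target = "prop.score", op = "gte", value = 0.5)),
      p = list(list(target = "data.disprot.disorder_content", op = "gte",
                    value = 0.9)))
  ))
}
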