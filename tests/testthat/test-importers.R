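test_that("the worked-example fixtures rebuild the five-source network", {
  db <- bg_build_worked_example()
  s <- bg_stats(db)
  expect_equal(s$entities, 5L)
  expect_equal(s$identifiers, 6L)
  expect_equal(s$relations_by_label$HAS_ID, 6L)
  expect_equal(s$relations_by_label$RELATED_WITH, 1L)
  expect_equal(s$relations_by_label$IS, 1L)
  expect_equal(s$relations_by_label$CONTAINS, 1L)
  types <- vapply(bg_entities(db), function(i) bg_get(db, i)$entity_type, "")
  expect_setequal(unname(types),
                  c("gene", "protein", "disease", "antigen", "epitope"))
})

test_that("cross-dataset records about one entity land on one node", {
  db <- bg_build_worked_example()
  # HGNC created gene CDKN1A; DisGeNET referenced it; one node remains
  expect_length(bg_entities(db, "gene"), 1)
  gene <- bg_entities(db, "gene")
  labels <- vapply(bg_neighbors(db, gene, direction = "any"),
                   function(nb) nb$relation$label, character(1))
  # the single gene node carries edges contributed by three importers
  expect_true(all(c("HAS_ID", "HAS_DATA", "FROM", "RELATED_WITH", "IS")
                  %in% labels))
  # antigen node shared by tantigen and iedb: CONTAINS deduplicated
  expect_length(bg_entities(db, "antigen"), 1)
})

test_that("re-importing every fixture is idempotent", {
  dir <- tempfile("we")
  paths <- bg_generate_fixture("worked_example", out_dir = dir)
  db <- bg_db()
  importers <- list(hgnc = bg_import_hgnc, disprot = bg_import_disprot,
                    disgenet = bg_import_disgenet,
                    tantigen = bg_import_tantigen, iedb = bg_import_iedb)
  for (nm in names(importers)) importers[[nm]](db, paths[[nm]])
  before <- bg_stats(db)
  for (nm in names(importers)) {
    rec <- importers[[nm]](db, paths[[nm]])
    expect_equal(rec$inserted, 0L)
  }
  expect_equal(bg_stats(db), before)
  unlink(dir, recursive = TRUE)
})

test_that("a DisGeNET row maps to two entities and a scored relation", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_symbol\tdisease_id\tdisease_name\tscore",
               "CDKN1A\tC0038356\tStomach Neoplasms\t0.9"), path)
  db <- bg_db()
  bg_import_disgenet(db, path)
  expect_equal(bg_stats(db)$entities, 2L)
  eid <- Filter(function(e) bg_get(db, e)$label == "RELATED_WITH", bg_edges(db))
  expect_length(eid, 1)
  rel <- bg_get(db, eid[[1]])
  expect_equal(rel$props$score, 0.9)
  gene <- bg_entities(db, "gene")
  expect_equal(bg_get(db, rel$source_id)$primary_identifier, "CDKN1A")
  expect_equal(bg_get(db, rel$target_id)$primary_identifier, "C0038356")
  unlink(path)
})

test_that("DisGeNET aborts on a missing required column, leaving the store pristine", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_symbol\tdisease_id", "CDKN1A\tC0038356"), path)
  db <- bg_build_worked_example()
  before <- db_fingerprint(db)
  expect_error(bg_import_disgenet(db, path), "score")
  expect_identical(db_fingerprint(db), before)
  unlink(path)
})

test_that("unparsable scores skip the row with a warning, conserving counts", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_symbol\tdisease_id\tdisease_name\tscore",
               "CDKN1A\tC0038356\tStomach Neoplasms\t0.9",
               "TP53\tC0006826\tNeoplasms\tnot-a-number"), path)
  db <- bg_db()
  expect_warning(rec <- bg_import_disgenet(db, path), "skipped")
  expect_equal(rec$records_read, 2L)
  expect_equal(rec$records_skipped, 1L)
  expect_equal(bg_stats(db)$entities, 2L)  # only the good row's entities
  unlink(path)
})

test_that("HGNC maps gene, identifiers, location and protein reference", {
  path <- tempfile(fileext = ".json")
  writeLines('[{"symbol": "CDKN1A", "ncbi_id": "1026",
                "location": "6p21.2", "uniprot": "P38936"},
               {"symbol": "ORPHAN1"},
               {"location": "1q1.1"}]', path)
  db <- bg_db()
  expect_warning(rec <- bg_import_hgnc(db, path), "no gene symbol")
  s <- bg_stats(db)
  expect_equal(s$entities, 3L)  # two genes + one protein
  expect_equal(s$relations_by_label$FROM, 1L)
  eid <- Filter(function(e) bg_get(db, e)$label == "FROM", bg_edges(db))[[1]]
  rel <- bg_get(db, eid)
  expect_equal(bg_get(db, rel$source_id)$entity_type, "protein")
  expect_equal(bg_get(db, rel$target_id)$entity_type, "gene")
  expect_equal(rec$records_skipped, 1L)
  unlink(path)
})

test_that("DisProt maps accessions, both identifiers and disorder content", {
  path <- tempfile(fileext = ".json")
  writeLines('[{"acc": "P38936", "disprot_id": "DP00016", "disorder_content": 0.9},
               {"acc": "P04637", "disprot_id": "DP00086", "disorder_content": 1.4,
                "taxon": "9606"}]', path)
  db <- bg_db()
  expect_warning(bg_import_disprot(db, path), "outside \\[0,1\\]")
  expect_length(bg_entities(db, "protein"), 2)
  expect_length(bg_entities(db, "organism"), 1)
  p <- bg_entities(db, "protein")[[1]]
  vals <- vapply(bg_neighbors(db, bg_keyword_search(db, "p38936")[[1]],
                              label = "HAS_ID", direction = "out"),
                 function(nb) nb$neighbor$value, character(1))
  expect_setequal(vals, c("P38936", "DP00016"))
  # out-of-range disorder content stored as-is
  stored <- bg_evaluate_condition(
    db, list(target = "data.disprot.disorder_content", op = "eq", value = 1.4),
    bg_keyword_search(db, "p04637")[[1]], "entity")
  expect_true(stored)
  unlink(path)
})

test_that("Tantigen and IEDB share epitopes and antigens through content addressing", {
  tpath <- tempfile(fileext = ".json")
  writeLines('[{"accession": "Ag002102", "full_name": "Tumor antigen",
                "gene": "CDKN1A", "epitopes": ["FAWERVRGL", "LLGRNSFEV"]},
               {"accession": "Ag000099", "epitopes": ["FAWERVRGL"]}]', tpath)
  ipath <- tempfile(fileext = ".tsv")
  writeLines(c("epitope_seq\tepitope_type\tantigen_id\torganism_taxon",
               "FAWERVRGL\tT cell\tAg002102\t9606"), ipath)
  db <- bg_db()
  bg_import_tantigen(db, tpath)
  rec <- bg_import_iedb(db, ipath)
  # shared epitope: one entity node, CONTAINS from both antigens
  expect_length(bg_entities(db, "epitope"), 2)
  ep <- bg_keyword_search(db, "fawervrgl")
  contains_in <- bg_neighbors(db, bg_entities(db, "antigen")[[1]],
                              label = "CONTAINS", direction = "out")
  expect_gte(length(contains_in), 1)
  s <- bg_stats(db)
  expect_equal(s$relations_by_label$IS, 1L)         # gene IS antigen
  expect_equal(s$relations_by_label$FROM, 1L)       # epitope FROM organism
  expect_length(bg_entities(db, "organism"), 1)
  unlink(c(tpath, ipath))
})

test_that("fixture generation is deterministic and validates the dialect", {
  d1 <- tempfile("f1"); d2 <- tempfile("f2")
  for (dialect in c("disgenet", "hgnc", "disprot", "tantigen", "iedb")) {
    p1 <- bg_generate_fixture(dialect, n = 20, seed = 9, out_dir = d1)
    p2 <- bg_generate_fixture(dialect, n = 20, seed = 9, out_dir = d2)
    expect_identical(readLines(p1[[1]]), readLines(p2[[1]]))
  }
  expect_error(bg_generate_fixture("genbank", out_dir = d1), "unknown dialect")
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("random DisGeNET imports create one edge per distinct row", {
  dir <- tempfile("dg")
  paths <- bg_generate_fixture("disgenet", n = 100, seed = 1, out_dir = dir)
  df <- utils::read.delim(paths[["disgenet"]], stringsAsFactors = FALSE)
  distinct_rows <- nrow(unique(df[c("gene_symbol", "disease_id", "score")]))
  db <- bg_db()
  bg_import_disgenet(db, paths[["disgenet"]])
  expect_equal(bg_stats(db)$relations_by_label$RELATED_WITH, distinct_rows)
  unlink(dir, recursive = TRUE)
})

test_that("every importer is transactional: an induced failure leaves no trace", {
  db <- bg_build_worked_example()
  before <- db_fingerprint(db)
  ct <- bg_import_contract(db)
  ct$begin_import("faulty")
  ct$map_entity(bg_entity("gene", "DOOMED1"))
  ct$map_entity(bg_entity("gene", "DOOMED2"))
  ct$map_relation("RELATED_WITH", bg_entity("gene", "DOOMED1"),
                  bg_entity("gene", "DOOMED2"), list(score = 0.5))
  ct$abort_import()
  expect_identical(db_fingerprint(db), before)
})

test_that("the import contract enforces begin-before-map and finish-once", {
  db <- bg_db()
  ct <- bg_import_contract(db)
  expect_error(ct$map_entity(bg_entity("gene", "X")), "begin_import")
  ct$begin_import("src")
  expect_error(ct$begin_import("src"), "already begun")
  ct$map_entity(bg_entity("gene", "X"))
  rec <- ct$finish_import()
  expect_equal(rec$inserted + rec$skipped, 1L)
  expect_error(ct$finish_import(), "begin_import")
})
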