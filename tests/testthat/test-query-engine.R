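test_that("conditions evaluate against data objects, identifiers and edge props", {
  db <- bg_build_worked_example()
  protein <- bg_entities(db, "protein")
  gene <- bg_entities(db, "gene")
  cond <- list(target = "data.disprot.disorder_content", op = "gte", value = 0.9)
  expect_true(bg_evaluate_condition(db, cond, protein, "entity"))
  cond$value <- 0.95
  expect_false(bg_evaluate_condition(db, cond, protein, "entity"))
  # missing attribute is false, never an error
  expect_false(bg_evaluate_condition(db, cond, gene, "entity"))
  # identifier target sees all HAS_ID values, case-insensitively
  id_cond <- list(target = "identifier", op = "eq", value = "dp00016")
  expect_true(bg_evaluate_condition(db, id_cond, protein, "entity"))
  expect_true(bg_evaluate_condition(
    db, list(target = "primary_id", op = "contains", value = "389"),
    protein, "entity"))
  # RELATED_WITH edge with score 0.9 passes gt 0.5
  eid <- Filter(function(e) bg_get(db, e)$label == "RELATED_WITH", bg_edges(db))[[1]]
  expect_true(bg_evaluate_condition(
    db, list(target = "prop.score", op = "gt", value = 0.5), eid, "relation"))
  expect_false(bg_evaluate_condition(
    db, list(target = "prop.missing", op = "gt", value = 0), eid, "relation"))
})

test_that("ordering ops against non-numeric stored values warn and are false", {
  db <- bg_db()
  txn <- bg_begin(db)
  e <- bg_upsert(db, bg_entity("gene", "G1"))
  d <- bg_upsert(db, bg_data("src", list(note = "high")))
  bg_upsert_relation(db, bg_relation("HAS_DATA", e$id, d$id))
  bg_commit(txn)
  cond <- list(target = "data.src.note", op = "gte", value = 1)
  expect_warning(res <- bg_evaluate_condition(db, cond, e$id, "entity"),
                 "non-numeric")
  expect_false(res)
})

test_that("the example cross-dataset query finds the worked-example binding", {
  db <- bg_build_worked_example()
  matches <- bg_execute(db, bg_example_query())
  expect_length(matches, 1)
  bound <- vapply(matches[[1]]$binding, function(i)
    bg_get(db, i)$primary_identifier, character(1))
  expect_equal(bound[["g"]], "CDKN1A")
  expect_equal(bound[["p"]], "P38936")
  expect_equal(bound[["d"]], "C0038356")
  expect_equal(bound[["a"]], "Ag002102")
  expect_equal(bound[["e"]], "FAWERVRGL")
})

test_that("any pattern on an empty store returns an empty list", {
  db <- bg_db()
  expect_length(bg_execute(db, bg_example_query()), 0)
})

test_that("matches are injective on entities and use distinct edges", {
  set.seed(41)
  n_matches <- 0L
  violations <- 0L
  for (rep in seq_len(20)) {
    db <- rand_store(sample(8:25, 1))
    matches <- bg_execute(db, rand_pattern())
    n_matches <- n_matches + length(matches)
    for (m in matches)
      if (anyDuplicated(m$binding) > 0 || anyDuplicated(m$edges) > 0)
        violations <- violations + 1L
  }
  # the worked example guarantees at least one nontrivial match is checked
  we <- bg_build_worked_example()
  m <- bg_execute(we, bg_example_query())[[1]]
  expect_false(anyDuplicated(m$binding) > 0)
  expect_gt(n_matches + 1L, 0L)
  expect_equal(violations, 0L)
})

test_that("the matcher agrees with brute-force enumeration on random instances", {
  set.seed(47)
  for (rep in seq_len(30)) {
    db <- rand_store(sample(5:30, 1))
    pattern <- rand_pattern()
    expect_identical(engine_keys(bg_execute(db, pattern)),
                     oracle_execute(db, pattern))
  }
})

test_that("tightening a numeric threshold never enlarges the result set", {
  set.seed(53)
  for (rep in seq_len(10)) {
    db <- rand_store(sample(10:30, 1))
    base <- list(match = list(
      nodes = list(x = "gene", y = "disease"),
      relations = list(list(from = "x", label = "RELATED_WITH", to = "y",
                            direction = "any", alias = "r"))),
      params = list(r = list(list(target = "prop.score", op = "gte",
                                  value = 0.5))))
    loose <- bg_execute(db, bg_parse_query(base))
    base$params$r[[1]]$value <- 0.9
    tight <- bg_execute(db, bg_parse_query(base))
    expect_true(all(engine_keys(tight) %in% engine_keys(loose)))
  }
})

test_that("branching matches decompose into the minimal linear paths", {
  db <- bg_build_worked_example()
  m <- bg_execute(db, bg_example_query())[[1]]
  paths <- bg_decompose_paths(db, m)
  # gene has degree 3; odd-degree vertices: disease, protein, epitope, gene
  expect_equal(odd_degree_count(db, unname(m$edges)), 4)
  expect_length(paths, 2)
  covered <- unlist(lapply(paths, `[[`, "edges"))
  expect_false(anyDuplicated(covered) > 0)       # edge-disjoint
  expect_setequal(covered, unname(m$edges))      # exact coverage
})

test_that("a linear two-edge match stays one path", {
  db <- bg_build_worked_example()
  q <- bg_parse_query('
   {"match": {"nodes": {"d": "disease", "g": "gene", "p": "protein"},
              "relations": [
                {"from": "g", "label": "RELATED_WITH", "to": "d"},
                {"from": "p", "label": "FROM", "to": "g"}]},
    "params": {}}')
  m <- bg_execute(db, q)[[1]]
  paths <- bg_decompose_paths(db, m)
  expect_length(paths, 1)
  expect_length(paths[[1]]$edges, 2)
  expect_length(paths[[1]]$nodes, 3)
})

test_that("tree decomposition matches the exhaustive minimum cover", {
  set.seed(59)
  for (rep in seq_len(25)) {
    tm <- rand_tree_match()
    paths <- bg_decompose_paths(tm$db, tm$match)
    eids <- unname(tm$match$edges)
    o <- odd_degree_count(tm$db, eids)
    expect_equal(length(paths), ceiling(o / 2))
    ends <- lapply(eids, function(e) {
      rel <- bg_get(tm$db, e); c(rel$source_id, rel$target_id)
    })
    expect_equal(length(paths), oracle_min_cover(ends))
    covered <- unlist(lapply(paths, `[[`, "edges"))
    expect_false(anyDuplicated(covered) > 0)
    expect_setequal(covered, eids)
    for (p in paths) {  # consecutive elements are incident
      for (i in seq_along(p$edges)) {
        rel <- bg_get(tm$db, p$edges[[i]])
        expect_setequal(c(rel$source_id, rel$target_id),
                        c(p$nodes[[i]], p$nodes[[i + 1]]))
      }
    }
  }
})

test_that("CSV export writes one row per (match, path) with RFC-4180 quoting", {
  db <- bg_build_worked_example()
  matches <- bg_execute(db, bg_example_query())
  path <- tempfile(fileext = ".csv")
  bg_export_results(db, matches, path, format = "csv")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(df), 2)  # one match, two paths
  expect_equal(df$match_index, c(1, 1))
  expect_equal(df$path_index, c(1, 2))
  expect_true("CDKN1A" %in% unlist(df))
  # empty result set: header-only CSV
  bg_export_results(db, list(), path, format = "csv")
  empty <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("match_index", "path_index") %in% names(empty)))
  unlink(path)
})

test_that("JSON export re-reads to the exact original bindings", {
  set.seed(61)
  for (rep in seq_len(10)) {
    db <- rand_store(sample(8:20, 1))
    matches <- bg_execute(db, rand_pattern(sample(2:3, 1)))
    path <- tempfile(fileext = ".json")
    bg_export_results(db, matches, path, format = "json")
    back <- bg_read_results(path)
    expect_equal(length(back), length(matches))
    for (i in seq_along(matches)) {
      expect_identical(back[[i]]$binding, matches[[i]]$binding)
      expect_identical(unname(back[[i]]$edges), unname(matches[[i]]$edges))
    }
    unlink(path)
  }
})

test_that("two runs on the same store produce byte-identical exports", {
  db <- bg_build_worked_example()
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  m1 <- bg_execute(db, bg_example_query())
  m2 <- bg_execute(db, bg_example_query())
  bg_export_results(db, m1, p1, format = "csv")
  bg_export_results(db, m2, p2, format = "csv")
  expect_identical(readLines(p1), readLines(p2))
  unlink(c(p1, p2))
})
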