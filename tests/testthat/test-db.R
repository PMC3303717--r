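# relational schema, ontology installation, statement execution with
# foreign-key substitution, transactions, pooling, subsumption retrieval

test_that("the schema creates its 13 core tables idempotently", {
  d <- fresh_db()
  on.exit(DBI::dbDisconnect(d$con))
  cat1 <- db_create_schema(d$con)   # second run on the same database
  expect_length(cat1$core_tables, 13L)
  expect_true(all(cat1$core_tables %in% DBI::dbListTables(d$con)))
  cat2 <- db_create_schema(d$con)
  expect_identical(cat1$core_tables, cat2$core_tables)
  # a foreign table coexists without collision
  DBI::dbExecute(d$con, "CREATE TABLE user_notes (id INTEGER PRIMARY KEY)")
  cat3 <- db_create_schema(d$con)
  expect_identical(cat3$core_tables, cat1$core_tables)
  expect_true("user_notes" %in% DBI::dbListTables(d$con))
  # schema version mismatch is a migration error
  DBI::dbExecute(d$con, "PRAGMA user_version = 99")
  expect_error(db_create_schema(d$con), "migration")
})

test_that("ontology installation matches closure size and is upsert-stable", {
  d <- fresh_db()
  on.exit(DBI::dbDisconnect(d$con))
  m <- install_mini(d$con)
  n1 <- list(
    terms = DBI::dbGetQuery(d$con, "SELECT COUNT(*) n FROM ontology_term")$n,
    cvpath = DBI::dbGetQuery(d$con, "SELECT COUNT(*) n FROM cvpath")$n)
  expect_equal(n1$terms, nrow(m$graph$terms))
  expect_equal(n1$cvpath, nrow(m$closure))
  n2 <- db_install_ontology(d$con, m$graph, m$closure)
  expect_equal(n2$terms, n1$terms)
  expect_equal(n2$cvpath, n1$cvpath)
})

test_that("the generated key of statement 48 substitutes into statement 49", {
  d <- fresh_db()
  on.exit(DBI::dbDisconnect(d$con))
  stmts <- list(
    gbloadr:::new_statement("insert", 48, "taxonomy",
                            c("organismName", "lineage"),
                            list("Testus testus", "Eukaryota")),
    gbloadr:::new_statement("insert", 49, "individual",
                            "identificationId", list(NA),
                            foreign_counts = 48,
                            foreign_columns = "identificationId"))
  res <- db_execute_statements(d$con, stmts, gi = 1L)
  expect_equal(res$status, "loaded")
  tax_key <- unname(res$keys[["48"]])
  ind <- DBI::dbGetQuery(d$con,
    "SELECT identificationId FROM individual WHERE individualId = ?",
    params = list(unname(res$keys[["49"]])))
  expect_equal(ind$identificationId, tax_key)
  expect_equal(nrow(db_audit_admissibility(d$con, mini()$triples,
                                           mini()$closure)), 0L)
})

test_that("an unordered statement list is rejected before execution", {
  d <- fresh_db()
  on.exit(DBI::dbDisconnect(d$con))
  stmts <- list(
    gbloadr:::new_statement("insert", 2, "individual", "identificationId",
                            list(NA), foreign_counts = 3,
                            foreign_columns = "identificationId"),
    gbloadr:::new_statement("insert", 3, "taxonomy", "organismName",
                            list("x")))
  res <- db_execute_statements(d$con, stmts, gi = 2L)
  expect_equal(res$status, "failed")
  expect_equal(DBI::dbGetQuery(d$con, "SELECT COUNT(*) n FROM individual")$n, 0L)
})

test_that("a failure mid-entry rolls back every row of the entry", {
  d <- fresh_db()
  on.exit(DBI::dbDisconnect(d$con))
  m <- install_mini(d$con)
  fx <- generate_entries(1, seed = 43, profile = "nested_gene_models")
  path <- tempfile()
  write_fixture(fx, path)
  e <- gb_read_entries(path)[[1]]
  stmts <- reason_entry(e, m)$statements
  before <- vapply(gbloadr:::CORE_TABLES, function(t)
    DBI::dbGetQuery(d$con, paste("SELECT COUNT(*) n FROM", t))$n, numeric(1))
  # poison a late statement: NOT NULL violation on sequence_feature.entryId
  k <- max(which(vapply(stmts, `[[`, character(1), "table") ==
                 "sequence_feature"))
  stmts[[k]]$foreign_counts <- stmts[[k]]$foreign_counts[-1]
  stmts[[k]]$foreign_columns <- stmts[[k]]$foreign_columns[-1]
  res <- db_execute_statements(d$con, stmts, gi = e$header$gi)
  expect_equal(res$status, "failed")
  expect_equal(res$failed_count, stmts[[k]]$count)
  after <- vapply(gbloadr:::CORE_TABLES, function(t)
    DBI::dbGetQuery(d$con, paste("SELECT COUNT(*) n FROM", t))$n, numeric(1))
  expect_identical(after, before)
})

test_that("select statements are get-or-create and maintain cvpath self paths", {
  d <- fresh_db()
  on.exit(DBI::dbDisconnect(d$con))
  s <- gbloadr:::new_statement("select", 1, "ontology_term",
                               c("accession", "name"),
                               list("local:novel", "novel"))
  r1 <- db_execute_statements(d$con, list(s))
  r2 <- db_execute_statements(d$con, list(s))
  expect_equal(r1$keys[["1"]], r2$keys[["1"]])
  self <- DBI::dbGetQuery(d$con,
    "SELECT COUNT(*) n FROM cvpath WHERE subjectId = ? AND objectId = ?",
    params = list(r1$keys[["1"]], r1$keys[["1"]]))
  expect_equal(self$n, 1L)
})

test_that("subsumption retrieval returns descendants through cvpath", {
  d <- fresh_db()
  on.exit(DBI::dbDisconnect(d$con))
  install_mini(d$con)
  # plant one entry with a feature typed mitochondrial_gene
  stmts <- list(
    gbloadr:::new_statement("select", 1, "taxonomy",
                            c("organismName", "lineage"),
                            list("Testus testus", "Eukaryota")),
    gbloadr:::new_statement("insert", 2, "entry",
                            c("gi", "accession", "taxonomyId"),
                            list(7001L, "MT00001", NA),
                            foreign_counts = 1, foreign_columns = "taxonomyId"),
    gbloadr:::new_statement("select", 3, "ontology_term",
                            c("accession", "name"),
                            list("SO:0000088", "mitochondrial_gene")),
    gbloadr:::new_statement("insert", 4, "sequence_feature",
                            c("entryId", "typeTermId", "rank", "spanStart",
                              "spanEnd", "strand", "featureKey"),
                            list(NA, NA, 0L, 1L, 900L, "forward", "gene"),
                            foreign_counts = c(2, 3),
                            foreign_columns = c("entryId", "typeTermId")))
  expect_equal(db_execute_statements(d$con, stmts)$status, "loaded")
  hits <- db_features_by_term(d$con, "gene")
  expect_equal(hits$type, "mitochondrial_gene")
  expect_equal(hits$entryAccession, "MT00001")
  expect_equal(nrow(db_features_by_term(d$con, "CDS")), 0L)
  expect_error(db_features_by_term(d$con, "no_such_term"), "unknown")
})

test_that("the connection pool leases, serializes and bounds its waits", {
  path <- tempfile(fileext = ".sqlite")
  con0 <- db_connect(path)
  db_create_schema(con0)
  DBI::dbDisconnect(con0)
  pool <- db_pool(path, size = 2L)
  l1 <- pool_lease(pool)
  l2 <- pool_lease(pool)
  expect_true(DBI::dbIsValid(l1$con) && DBI::dbIsValid(l2$con))
  pool_release(l1)
  pool_release(l2)
  # size 1: serialized leases both succeed
  p1 <- db_pool(path, size = 1L, timeout_s = 0.2)
  a <- pool_lease(p1)
  pool_release(a)
  b <- pool_lease(p1)
  pool_release(b)
  # exhaustion times out
  c1 <- pool_lease(p1)
  expect_error(pool_lease(p1), "exhausted")
  pool_release(c1)
  pool_close(p1)
  expect_error(pool_lease(p1), "closed")
  pool_close(pool)
})
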