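#' @title Ontological relational schema and statement executor
#' @description Owns the Molecular Biodiversity relational schema
#'   (MolecularData core plus minimal Collection/Taxonomy areas), installs
#'   the ontology terms and their precomputed is_a closure (the CVPath
#'   table), and executes ordered statement lists with run-time foreign-key
#'   substitution inside one transaction per entry.  All features share a
#'   single table typed by ontology terms; relationships and annotations
#'   live in common tables keyed by the feature identifier.
#' @name db-loader
NULL

SCHEMA_VERSION <- 1L

CORE_TABLES <- c("ontology_term", "cvpath", "individual", "entry", "sequence",
                 "sequence_feature", "feature_portion", "feature_annotation",
                 "feature_relationship", "reference", "reference_evidence",
                 "taxonomy", "collection_event")

TABLE_PK <- c(ontology_term = "termId", cvpath = "cvpathId",
              individual = "individualId", entry = "entryId",
              sequence = "sequenceId", sequence_feature = "featureId",
              feature_portion = "portionId", feature_annotation = "annotationId",
              feature_relationship = "relationshipId", reference = "referenceId",
              reference_evidence = "evidenceId", taxonomy = "taxonomyId",
              collection_event = "collectionEventId", load_log = "logId")

COLLECTION_COLUMNS <- c(
  "bioMaterial", "breed", "cellLine", "cellType", "clone", "cloneLib",
  "collectedBy", "collectionDate", "country", "cultivar", "cultureCollection",
  "devStage", "ecotype", "environmentalSample", "haplotype", "identifiedBy",
  "isolate", "isolationSource", "labHost", "latLon", "popVariant", "serotype",
  "serovar", "sex", "specificHost", "specimenVoucher", "strain", "subClone",
  "subSpecies", "subStrain", "tissueLib", "tissueType", "variety")

#' Open a connection to the embedded database
#'
#' @param db_path file path of the SQLite database (created on demand), or
#'   `":memory:"`.
#' @return a DBI connection with foreign keys enforced.
#' @export
db_connect <- function(db_path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), db_path)
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  con
}

schema_ddl <- function() {
  coll_cols <- paste(sprintf("  %s TEXT", COLLECTION_COLUMNS), collapse = ",\n")
  c(
    "CREATE TABLE IF NOT EXISTS ontology_term (
       termId INTEGER PRIMARY KEY,
       accession TEXT NOT NULL UNIQUE,
       name TEXT,
       namespace TEXT,
       isObsolete INTEGER NOT NULL DEFAULT 0)",
    "CREATE TABLE IF NOT EXISTS cvpath (
       cvpathId INTEGER PRIMARY KEY,
       subjectId INTEGER NOT NULL REFERENCES ontology_term(termId),
       objectId INTEGER NOT NULL REFERENCES ontology_term(termId),
       relationship TEXT NOT NULL,
       distance INTEGER NOT NULL,
       UNIQUE (subjectId, objectId, relationship))",
    "CREATE TABLE IF NOT EXISTS taxonomy (
       taxonomyId INTEGER PRIMARY KEY,
       organismName TEXT,
       lineage TEXT,
       ncbiTaxonId TEXT)",
    "CREATE TABLE IF NOT EXISTS individual (
       individualId INTEGER PRIMARY KEY,
       identificationId INTEGER REFERENCES taxonomy(taxonomyId))",
    sprintf("CREATE TABLE IF NOT EXISTS collection_event (
       collectionEventId INTEGER PRIMARY KEY,
       individualId INTEGER REFERENCES individual(individualId),\n%s)",
       coll_cols),
    "CREATE TABLE IF NOT EXISTS entry (
       entryId INTEGER PRIMARY KEY,
       gi INTEGER NOT NULL UNIQUE,
       accession TEXT,
       version TEXT,
       locusName TEXT,
       definition TEXT,
       sequenceLength INTEGER,
       moleculeType TEXT,
       topology TEXT,
       divisionCode TEXT,
       modificationDate TEXT,
       keywords TEXT,
       taxonomyId INTEGER REFERENCES taxonomy(taxonomyId),
       individualId INTEGER REFERENCES individual(individualId))",
    "CREATE TABLE IF NOT EXISTS sequence (
       sequenceId INTEGER PRIMARY KEY,
       entryId INTEGER NOT NULL REFERENCES entry(entryId),
       length INTEGER)",
    "CREATE TABLE IF NOT EXISTS sequence_feature (
       featureId INTEGER PRIMARY KEY,
       entryId INTEGER NOT NULL REFERENCES entry(entryId),
       typeTermId INTEGER NOT NULL REFERENCES ontology_term(termId),
       rank INTEGER,
       spanStart INTEGER,
       spanEnd INTEGER,
       strand TEXT,
       featureKey TEXT)",
    "CREATE TABLE IF NOT EXISTS feature_portion (
       portionId INTEGER PRIMARY KEY,
       featureId INTEGER NOT NULL REFERENCES sequence_feature(featureId),
       start INTEGER,
       end INTEGER,
       strand TEXT,
       partial5 INTEGER,
       partial3 INTEGER,
       betweenBases INTEGER,
       remoteAccession TEXT,
       rank INTEGER)",
    "CREATE TABLE IF NOT EXISTS feature_annotation (
       annotationId INTEGER PRIMARY KEY,
       featureId INTEGER NOT NULL REFERENCES sequence_feature(featureId),
       typeTermId INTEGER NOT NULL REFERENCES ontology_term(termId),
       qualifier TEXT,
       value TEXT)",
    "CREATE TABLE IF NOT EXISTS feature_relationship (
       relationshipId INTEGER PRIMARY KEY,
       subjectId INTEGER NOT NULL REFERENCES sequence_feature(featureId),
       objectId INTEGER NOT NULL REFERENCES sequence_feature(featureId),
       relTypeTermId INTEGER NOT NULL REFERENCES ontology_term(termId),
       provenance TEXT,
       CHECK (subjectId <> objectId))",
    "CREATE TABLE IF NOT EXISTS reference (
       referenceId INTEGER PRIMARY KEY,
       entryId INTEGER NOT NULL REFERENCES entry(entryId),
       ordinal INTEGER,
       authors TEXT,
       title TEXT,
       journal TEXT,
       pubmedId INTEGER,
       citedRanges TEXT)",
    "CREATE TABLE IF NOT EXISTS reference_evidence (
       evidenceId INTEGER PRIMARY KEY,
       featureId INTEGER NOT NULL REFERENCES sequence_feature(featureId),
       referenceId INTEGER NOT NULL REFERENCES reference(referenceId))",
    "CREATE TABLE IF NOT EXISTS load_log (
       logId INTEGER PRIMARY KEY,
       gi INTEGER,
       sequenceLength INTEGER,
       featureTableLength INTEGER,
       nFeatures INTEGER,
       nStatements INTEGER,
       parsingTimeMs REAL,
       reasoningTimeMs REAL,
       insertTimeMs REAL,
       totalTimeMs REAL)",
    "CREATE INDEX IF NOT EXISTS ix_cvpath_object ON cvpath(objectId)",
    "CREATE INDEX IF NOT EXISTS ix_feature_type ON sequence_feature(typeTermId)",
    "CREATE INDEX IF NOT EXISTS ix_rel_subject ON feature_relationship(subjectId)",
    "CREATE INDEX IF NOT EXISTS ix_rel_object ON feature_relationship(objectId)",
    "CREATE INDEX IF NOT EXISTS ix_annotation_feature ON feature_annotation(featureId)"
  )
}

#' Create (or verify) the ontological relational schema
#'
#' Creates the 13 core tables — ontology_term, cvpath, individual, entry,
#' sequence, sequence_feature, feature_portion, feature_annotation,
#' feature_relationship, reference, reference_evidence, taxonomy,
#' collection_event — plus an auxiliary load_log metrics table and the
#' supporting indexes.  Idempotent: re-running on the same database is a
#' no-op.  A database created by a different schema version is rejected.
#'
#' @param con DBI connection from [db_connect()].
#' @return the schema catalog: list(core_tables, aux_tables, primary_keys,
#'   version).
#' @export
db_create_schema <- function(con) {
  ver <- DBI::dbGetQuery(con, "PRAGMA user_version")[[1]]
  if (ver != 0L && ver != SCHEMA_VERSION)
    stop("schema migration error: database has schema version ", ver,
         ", this package expects ", SCHEMA_VERSION)
  for (ddl in schema_ddl()) DBI::dbExecute(con, ddl)
  DBI::dbExecute(con, sprintf("PRAGMA user_version = %d", SCHEMA_VERSION))
  list(core_tables = CORE_TABLES, aux_tables = "load_log",
       primary_keys = TABLE_PK, version = SCHEMA_VERSION)
}

#' Install ontology terms and their is_a closure into the database
#'
#' Terms are upserted by accession; closure rows land in cvpath with a
#' uniqueness constraint on (subject, object, relationship), so
#' reinstalling the same snapshot leaves counts unchanged.
#'
#' @param con DBI connection (schema must exist).
#' @param graph `so_graph` from [so_load_obo()].
#' @param closure data.frame from [so_is_a_closure()].
#' @return list(terms = , cvpath = ) row counts after installation.
#' @export
db_install_ontology <- function(con, graph, closure) {
  DBI::dbBegin(con)
  on.exit(if (DBI::dbIsValid(con)) try(DBI::dbRollback(con), silent = TRUE))
  for (i in seq_len(nrow(graph$terms))) {
    DBI::dbExecute(con,
      "INSERT INTO ontology_term (accession, name, namespace, isObsolete)
       VALUES (?, ?, ?, ?)
       ON CONFLICT(accession) DO UPDATE SET name = excluded.name,
         namespace = excluded.namespace, isObsolete = excluded.isObsolete",
      params = list(graph$terms$accession[i], graph$terms$name[i],
                    graph$terms$namespace[i],
                    as.integer(graph$terms$obsolete[i])))
  }
  ids <- DBI::dbGetQuery(con, "SELECT termId, accession FROM ontology_term")
  lut <- stats::setNames(ids$termId, ids$accession)
  for (i in seq_len(nrow(closure))) {
    DBI::dbExecute(con,
      "INSERT OR IGNORE INTO cvpath (subjectId, objectId, relationship, distance)
       VALUES (?, ?, ?, ?)",
      params = list(lut[[closure$subject[i]]], lut[[closure$object[i]]],
                    closure$relationship[i], closure$distance[i]))
  }
  DBI::dbCommit(con)
  on.exit(NULL)
  list(terms = DBI::dbGetQuery(con, "SELECT COUNT(*) n FROM ontology_term")$n,
       cvpath = DBI::dbGetQuery(con, "SELECT COUNT(*) n FROM cvpath")$n)
}

#' Execute an ordered statement list inside one transaction
#'
#' Statements run in count order.  Before execution, every foreign count is
#' substituted with the database key generated by (or selected for) the
#' cited statement.  `select` statements are get-or-create: the row
#' matching the given columns is looked up and its primary key captured; if
#' absent the row is inserted.  A `select` that creates a new ontology_term
#' also inserts its distance-0 cvpath self path so subsumption queries see
#' the new term.  On any error the whole entry rolls back and a failed
#' LoadResult carries the offending count.
#'
#' @param con DBI connection.
#' @param statements validated statement list from [build_statements()].
#' @param gi entry identifier recorded in the result.
#' @return LoadResult: list(gi, status ("loaded"/"failed"), n_statements,
#'   keys (count -> generated key), reason, failed_count).
#' @export
db_execute_statements <- function(con, statements, gi = NA_integer_) {
  ok <- tryCatch({ validate_statements(statements); TRUE },
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok))
    return(list(gi = gi, status = "failed", n_statements = 0L,
                keys = numeric(0), reason = ok, failed_count = NA_integer_))
  keys <- new.env(parent = emptyenv())
  DBI::dbBegin(con)
  failed <- NULL
  for (s in statements) {
    res <- tryCatch({
      vals <- s$values
      for (k in seq_along(s$foreign_counts)) {
        ix <- which(s$columns == s$foreign_columns[k])[1]
        vals[[ix]] <- get(as.character(s$foreign_counts[k]), envir = keys)
      }
      key <- if (s$kind == "select") db_select_or_insert(con, s, vals)
             else db_insert(con, s, vals)
      assign(as.character(s$count), key, envir = keys)
      NULL
    }, error = function(e) list(count = s$count, msg = conditionMessage(e)))
    if (!is.null(res)) { failed <- res; break }
  }
  if (!is.null(failed)) {
    DBI::dbRollback(con)
    return(list(gi = gi, status = "failed", n_statements = length(statements),
                keys = numeric(0),
                reason = failed$msg, failed_count = failed$count))
  }
  DBI::dbCommit(con)
  list(gi = gi, status = "loaded", n_statements = length(statements),
       keys = stats::setNames(
         vapply(ls(keys), function(k) get(k, envir = keys), numeric(1)),
         ls(keys)),
       reason = NA_character_, failed_count = NA_integer_)
}

db_insert <- function(con, s, vals) {
  sql <- sprintf("INSERT INTO %s (%s) VALUES (%s)", s$table,
                 paste(s$columns, collapse = ", "),
                 paste(rep("?", length(s$columns)), collapse = ", "))
  DBI::dbExecute(con, sql, params = unname(vals))
  DBI::dbGetQuery(con, "SELECT last_insert_rowid() AS k")$k
}

db_select_or_insert <- function(con, s, vals) {
  pk <- TABLE_PK[[s$table]]
  where <- paste(vapply(seq_along(s$columns), function(i) {
    if (is.null(vals[[i]]) || (length(vals[[i]]) == 1L && is.na(vals[[i]])))
      sprintf("%s IS NULL", s$columns[i])
    else sprintf("%s = ?", s$columns[i])
  }, character(1)), collapse = " AND ")
  bind <- vals[!vapply(vals, function(v)
    is.null(v) || (length(v) == 1L && is.na(v)), logical(1))]
  sql <- sprintf("SELECT %s AS k FROM %s WHERE %s LIMIT 1", pk, s$table, where)
  hit <- DBI::dbGetQuery(con, sql, params = unname(bind))
  if (nrow(hit)) return(hit$k[1])
  key <- db_insert(con, s, vals)
  if (s$table == "ontology_term") {
    # keep the closure total: a term created at load time is its own
    # distance-0 subsumption match
    DBI::dbExecute(con,
      "INSERT OR IGNORE INTO cvpath (subjectId, objectId, relationship, distance)
       VALUES (?, ?, 'is_a', 0)", params = list(key, key))
  }
  key
}

#' Referential-integrity audit over a loaded database
#'
#' Counts orphan rows in every child table; all counts must be zero after
#' any load batch.
#'
#' @param con DBI connection.
#' @return named integer vector of orphan counts.
#' @export
db_audit_integrity <- function(con) {
  checks <- c(
    feature_portion = "SELECT COUNT(*) n FROM feature_portion p LEFT JOIN
      sequence_feature f ON p.featureId = f.featureId WHERE f.featureId IS NULL",
    feature_annotation = "SELECT COUNT(*) n FROM feature_annotation a LEFT JOIN
      sequence_feature f ON a.featureId = f.featureId WHERE f.featureId IS NULL",
    feature_relationship = "SELECT COUNT(*) n FROM feature_relationship r
      LEFT JOIN sequence_feature s ON r.subjectId = s.featureId
      LEFT JOIN sequence_feature o ON r.objectId = o.featureId
      WHERE s.featureId IS NULL OR o.featureId IS NULL",
    reference_evidence = "SELECT COUNT(*) n FROM reference_evidence e
      LEFT JOIN sequence_feature f ON e.featureId = f.featureId
      LEFT JOIN reference r ON e.referenceId = r.referenceId
      WHERE f.featureId IS NULL OR r.referenceId IS NULL",
    sequence_feature = "SELECT COUNT(*) n FROM sequence_feature f LEFT JOIN
      entry e ON f.entryId = e.entryId WHERE e.entryId IS NULL",
    sequence = "SELECT COUNT(*) n FROM sequence s LEFT JOIN entry e ON
      s.entryId = e.entryId WHERE e.entryId IS NULL")
  vapply(checks, function(sql) as.integer(DBI::dbGetQuery(con, sql)$n),
         integer(1))
}

#' Admissibility audit: replay the rule-engine invariant at database level
#'
#' Verifies that every feature_relationship row's (subject type,
#' relationship, object type) is admissible under the ontology.
#'
#' @param con DBI connection.
#' @param triples admissible triples.
#' @param closure is_a closure.
#' @return data.frame of violating rows (zero rows when the audit passes).
#' @export
db_audit_admissibility <- function(con, triples, closure) {
  rows <- DBI::dbGetQuery(con, "
    SELECT st.accession AS subjectType, rt.name AS relName,
           ot.accession AS objectType, r.relationshipId
    FROM feature_relationship r
    JOIN sequence_feature s ON r.subjectId = s.featureId
    JOIN sequence_feature o ON r.objectId = o.featureId
    JOIN ontology_term st ON s.typeTermId = st.termId
    JOIN ontology_term ot ON o.typeTermId = ot.termId
    JOIN ontology_term rt ON r.relTypeTermId = rt.termId")
  if (nrow(rows) == 0L) return(rows)
  bad <- !vapply(seq_len(nrow(rows)), function(i)
    so_relationship_allowed(triples, closure, rows$subjectType[i],
                            rows$relName[i], rows$objectType[i]), logical(1))
  rows[bad, , drop = FALSE]
}

#' Retrieve features by ontology term with subsumption
#'
#' One cvpath join implements the subsumption inference: asking for
#' features typed "gene" also retrieves those typed "mitochondrial gene".
#'
#' @param con DBI connection.
#' @param accession_or_name term accession (SO:...) or term name.
#' @return data.frame(featureId, entryAccession, type, spanStart, spanEnd,
#'   strand) ordered by entry accession and feature rank.
#' @export
db_features_by_term <- function(con, accession_or_name) {
  root <- DBI::dbGetQuery(con,
    "SELECT termId FROM ontology_term WHERE accession = ? OR name = ?",
    params = list(accession_or_name, accession_or_name))
  if (nrow(root) == 0L)
    stop("unknown ontology term: ", accession_or_name)
  DBI::dbGetQuery(con, "
    SELECT f.featureId, e.accession AS entryAccession, t.name AS type,
           f.spanStart, f.spanEnd, f.strand
    FROM sequence_feature f
    JOIN entry e ON f.entryId = e.entryId
    JOIN ontology_term t ON f.typeTermId = t.termId
    WHERE f.typeTermId IN
      (SELECT subjectId FROM cvpath WHERE objectId = ? AND relationship = 'is_a')
    ORDER BY e.accession, f.rank", params = list(root$termId[1]))
}

# ---- connection pool -----------------------------------------------------

#' Create a bounded connection pool over the embedded database
#'
#' Connections are opened lazily up to `size`, reused across entry loads,
#' and never shared by two concurrent lessees.  Leasing from an exhausted
#' pool waits up to `timeout_s` seconds before failing.
#'
#' @param db_path database file path.
#' @param size maximum number of pooled connections.
#' @param timeout_s bounded wait on exhaustion, in seconds.
#' @return a `db_pool` object.
#' @export
db_pool <- function(db_path, size = 2L, timeout_s = 5) {
  pool <- new.env(parent = emptyenv())
  pool$db_path <- db_path
  pool$size <- as.integer(size)
  pool$free <- list()
  pool$n_open <- 0L
  pool$closed <- FALSE
  pool$timeout_s <- timeout_s
  class(pool) <- "db_pool"
  pool
}

#' Lease a connection from the pool
#' @param pool a `db_pool`.
#' @return list(con, pool) — return it with [pool_release()].
#' @export
pool_lease <- function(pool) {
  if (pool$closed) stop("connection pool is closed")
  deadline <- Sys.time() + pool$timeout_s
  repeat {
    if (length(pool$free)) {
      con <- pool$free[[1]]
      pool$free <- pool$free[-1]
      return(list(con = con, pool = pool))
    }
    if (pool$n_open < pool$size) {
      con <- db_connect(pool$db_path)
      pool$n_open <- pool$n_open + 1L
      return(list(con = con, pool = pool))
    }
    if (Sys.time() > deadline)
      stop("connection pool exhausted: ", pool$size,
           " leases outstanding after ", pool$timeout_s, "s wait")
    Sys.sleep(0.01)
  }
}

#' Return a leased connection to its pool
#' @param lease object from [pool_lease()].
#' @export
pool_release <- function(lease) {
  if (lease$pool$closed) {
    DBI::dbDisconnect(lease$con)
    return(invisible(NULL))
  }
  lease$pool$free <- c(lease$pool$free, list(lease$con))
  invisible(NULL)
}

#' Close a pool and its idle connections
#' @param pool a `db_pool`.
#' @export
pool_close <- function(pool) {
  for (con in pool$free) try(DBI::dbDisconnect(con), silent = TRUE)
  pool$free <- list()
  pool$closed <- TRUE
  invisible(NULL)
}
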