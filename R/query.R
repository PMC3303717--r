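#' @title Ontological query engine with subsumption expansion
#' @description Compiles query trees of the form
#'   `term memberOf (term hasMember (term hasAnnotation name=value))` into
#'   SQL over the loaded schema.  Every term is expanded to its descendant
#'   set through the precomputed cvpath closure (distance >= 0, so exact
#'   matches are included), and memberOf/hasMember chains traverse the
#'   transitive closure of stored part_of/member_of feature relationships:
#'   a gene "hasMember" its CDS through the intervening mRNA.
#' @name query-engine
NULL

#' Parse a parenthesized ontological query expression
#'
#' Grammar: `node := term [ (memberOf|hasMember) '(' node ')' |
#' hasAnnotation name = value ]`.  Terms may be SO accessions or term
#' names; annotation values may be double-quoted.
#'
#' @param text the query expression.
#' @return a `query_node`: list(term, rel, child, annotation).
#' @export
parse_query <- function(text) {
  toks <- regmatches(text, gregexpr(
    "\"[^\"]*\"|[A-Za-z_][A-Za-z0-9_:.]*|[()=]", text))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function(expect = NULL) {
    t <- peek()
    if (is.na(t)) stop("query parse error: unexpected end of expression")
    if (!is.null(expect) && t != expect)
      stop("query parse error: expected '", expect, "' but found '", t, "'")
    pos <<- pos + 1L
    t
  }
  parse_node <- function() {
    term <- take()
    if (term %in% c("memberOf", "hasMember", "hasAnnotation", "(", ")", "="))
      stop("query parse error: expected a term, found '", term, "'")
    node <- list(term = term, rel = NULL, child = NULL, annotation = NULL)
    nxt <- peek()
    if (!is.na(nxt) && nxt %in% c("memberOf", "hasMember")) {
      node$rel <- take()
      take("(")
      node$child <- parse_node()
      take(")")
    } else if (!is.na(nxt) && nxt == "hasAnnotation") {
      take()
      name <- take()
      take("=")
      value <- take()
      if (startsWith(value, "\""))
        value <- substr(value, 2L, nchar(value) - 1L)
      node$annotation <- list(name = name, value = value)
    }
    structure(node, class = "query_node")
  }
  out <- parse_node()
  if (!is.na(peek()))
    stop("query parse error: trailing tokens from '", peek(), "'")
  out
}

query_term_id <- function(con, term) {
  r <- DBI::dbGetQuery(con,
    "SELECT termId FROM ontology_term WHERE accession = ? OR name = ?",
    params = list(term, term))
  if (nrow(r) == 0L) stop("query compile error: unknown term '", term, "'")
  r$termId[1]
}

chain_term_ids <- function(con) {
  # chain edges match part_of or member_of rows; derives_from is excluded
  r <- DBI::dbGetQuery(con,
    "SELECT termId FROM ontology_term WHERE accession IN
       ('local:part_of', 'local:member_of')")
  r$termId
}

annotation_term_sql <- function(con, name) {
  routing <- gb_qualifier_routing()
  hit <- routing$target[routing$qualifier == name & routing$route == "annotation"]
  acc <- if (length(hit)) hit[1] else paste0("local:", name)
  r <- DBI::dbGetQuery(con,
    "SELECT termId FROM ontology_term WHERE accession = ?", params = list(acc))
  if (nrow(r) == 0L)
    stop("query compile error: unknown annotation qualifier '", name, "'")
  r$termId[1]
}

#' Compile a query tree to SQL
#'
#' @param node a `query_node` from [parse_query()].
#' @param con DBI connection (terms are resolved against the installed
#'   ontology).
#' @param like when TRUE the annotation value matches as a substring
#'   (SQL LIKE); default is exact, case-sensitive equality.
#' @return list(sql, params): a SELECT over sequence_feature returning
#'   featureId.
#' @export
compile_query <- function(node, con, like = FALSE) {
  rel_ids <- chain_term_ids(con)
  rel_in <- paste(rel_ids, collapse = ", ")
  params <- list()
  compile_node <- function(nd) {
    tid <- query_term_id(con, nd$term)
    conds <- sprintf(
      "f.typeTermId IN (SELECT subjectId FROM cvpath WHERE objectId = %d AND relationship = 'is_a')",
      tid)
    if (!is.null(nd$annotation)) {
      atid <- annotation_term_sql(con, nd$annotation$name)
      op <- if (like) "LIKE" else "="
      params[[length(params) + 1L]] <<- if (like)
        paste0("%", nd$annotation$value, "%") else nd$annotation$value
      conds <- c(conds, sprintf(
        "EXISTS (SELECT 1 FROM feature_annotation fa WHERE fa.featureId = f.featureId AND fa.typeTermId = %d AND fa.value %s ?)",
        atid, op))
    }
    if (!is.null(nd$rel)) {
      child_sql <- compile_node(nd$child)
      if (nd$rel == "memberOf") {
        # f is (transitively) a member/part of some feature in the child set
        chain <- sprintf(
          "f.featureId IN (WITH RECURSIVE up(id) AS (
             SELECT fr.subjectId FROM feature_relationship fr
               WHERE fr.objectId IN (%s) AND fr.relTypeTermId IN (%s)
             UNION
             SELECT fr.subjectId FROM feature_relationship fr
               JOIN up ON fr.objectId = up.id
               WHERE fr.relTypeTermId IN (%s))
           SELECT id FROM up)", child_sql, rel_in, rel_in)
      } else {
        # hasMember: some feature of the child set is transitively part of f
        chain <- sprintf(
          "f.featureId IN (WITH RECURSIVE down(id) AS (
             SELECT fr.objectId FROM feature_relationship fr
               WHERE fr.subjectId IN (%s) AND fr.relTypeTermId IN (%s)
             UNION
             SELECT fr.objectId FROM feature_relationship fr
               JOIN down ON fr.subjectId = down.id
               WHERE fr.relTypeTermId IN (%s))
           SELECT id FROM down)", child_sql, rel_in, rel_in)
      }
      conds <- c(conds, chain)
    }
    sprintf("SELECT f.featureId FROM sequence_feature f WHERE %s",
            paste(conds, collapse = " AND "))
  }
  inner <- compile_node(node)
  sql <- sprintf("
    SELECT f.featureId, e.accession AS entryAccession, t.name AS type,
           f.spanStart, f.spanEnd, f.strand
    FROM sequence_feature f
    JOIN entry e ON f.entryId = e.entryId
    JOIN ontology_term t ON f.typeTermId = t.termId
    WHERE f.featureId IN (%s)
    ORDER BY e.accession, f.rank", inner)
  list(sql = sql, params = params)
}

#' Execute an ontological query
#'
#' @param con DBI connection to a loaded database.
#' @param query a `query_node` or a query expression string.
#' @param like substring matching for the annotation value.
#' @return data.frame(featureId, entryAccession, type, spanStart, spanEnd,
#'   strand), deterministically ordered by entry accession and feature
#'   rank.
#' @export
run_query <- function(con, query, like = FALSE) {
  node <- if (is.character(query)) parse_query(query) else query
  compiled <- compile_query(node, con, like = like)
  if (length(compiled$params))
    DBI::dbGetQuery(con, compiled$sql, params = compiled$params)
  else DBI::dbGetQuery(con, compiled$sql)
}
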