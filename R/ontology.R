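#' @title Sequence Ontology knowledge: closure, admissibility, mappings
#' @description Loads an OBO 1.2 flat ontology, computes the transitive
#'   closure of the is_a hierarchy (the content of the CVPath table) and the
#'   admissible (subject type, relationship, object type) triples that the
#'   rule engine consults, and owns the bundled feature-key and qualifier
#'   mapping tables.  The closure and triples are computed once at setup
#'   time; loading never recomputes them.
#' @name so-ontology
NULL

#' Load an OBO 1.2 flat ontology
#'
#' Parses `[Term]` stanzas (id, name, namespace, is_obsolete, is_a,
#' relationship lines).  Unknown relationship types are preserved but play
#' no role in closure or admissibility.  A cyclic is_a graph is rejected
#' with one witness cycle.
#'
#' @param x path to an .obo file, or the OBO text itself (if it contains a
#'   newline or a `[Term]` stanza).
#' @return an object of class `so_graph`: list(terms, is_a, rel) where
#'   terms is a data.frame(accession, name, namespace, obsolete), is_a a
#'   data.frame(child, parent) and rel a data.frame(subject, relationship,
#'   object).
#' @export
so_load_obo <- function(x) {
  text <- if (grepl("\n", x) || grepl("\\[Term\\]", x)) x else
    paste(readLines(x, warn = FALSE), collapse = "\n")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0L)
    stop("OBO load error: no [Term] stanzas found")
  stanza_ends <- c(stanza_starts[-1] - 1L, length(lines))
  terms <- list(); is_a <- list(); rel <- list()
  for (k in seq_along(stanza_starts)) {
    blk <- lines[stanza_starts[k]:stanza_ends[k]]
    blk <- blk[!grepl("^\\s*$", blk) & !startsWith(blk, "[")]
    fields <- regmatches(blk, regexec("^([a-z_]+):\\s*(.*)$", blk))
    kv <- do.call(rbind, lapply(fields[lengths(fields) == 3L],
                                function(f) c(f[2], f[3])))
    if (is.null(kv)) next
    get1 <- function(key) {
      v <- kv[kv[, 1] == key, 2]
      if (length(v)) v[1] else ""
    }
    acc <- get1("id")
    if (!nzchar(acc)) next
    obsolete <- identical(tolower(get1("is_obsolete")), "true")
    terms[[length(terms) + 1L]] <- data.frame(
      accession = acc, name = get1("name"), namespace = get1("namespace"),
      obsolete = obsolete, stringsAsFactors = FALSE)
    for (v in kv[kv[, 1] == "is_a", 2]) {
      parent <- trimws(sub("!.*$", "", v))
      is_a[[length(is_a) + 1L]] <- data.frame(child = acc, parent = parent,
                                              stringsAsFactors = FALSE)
    }
    for (v in kv[kv[, 1] == "relationship", 2]) {
      v <- trimws(sub("!.*$", "", v))
      parts <- strsplit(v, "\\s+")[[1]]
      if (length(parts) >= 2L)
        rel[[length(rel) + 1L]] <- data.frame(
          subject = acc, relationship = parts[1], object = parts[2],
          stringsAsFactors = FALSE)
    }
  }
  terms <- do.call(rbind, terms)
  if (anyDuplicated(terms$accession))
    stop("OBO load error: duplicate term accession: ",
         terms$accession[duplicated(terms$accession)][1])
  is_a <- if (length(is_a)) do.call(rbind, is_a) else
    data.frame(child = character(0), parent = character(0))
  rel <- if (length(rel)) do.call(rbind, rel) else
    data.frame(subject = character(0), relationship = character(0),
               object = character(0))
  obs <- terms$accession[terms$obsolete]
  live_isa <- is_a[!(is_a$child %in% obs) & !(is_a$parent %in% obs), , drop = FALSE]
  if (nrow(live_isa)) {
    g <- igraph::graph_from_data_frame(live_isa, directed = TRUE)
    if (!igraph::is_dag(g)) {
      cyc <- so_find_cycle(live_isa)
      stop("OBO load error: cyclic is_a hierarchy: ",
           paste(cyc, collapse = " -> "))
    }
  }
  structure(list(terms = terms, is_a = is_a, rel = rel), class = "so_graph")
}

# one directed cycle in an edge list, by DFS
so_find_cycle <- function(edges) {
  adj <- split(edges$parent, edges$child)
  state <- new.env(parent = emptyenv())
  path <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    st <- mget(v, envir = state, ifnotfound = "white")[[1]]
    if (st == "grey") {
      found <<- c(path[which(path == v)[1]:length(path)], v)
      return()
    }
    if (st == "black") return()
    assign(v, "grey", envir = state)
    path <<- c(path, v)
    for (w in adj[[v]] %||% character(0)) visit(w)
    path <<- path[-length(path)]
    assign(v, "black", envir = state)
  }
  for (v in unique(edges$child)) visit(v)
  found
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute the is_a transitive closure (CVPath content)
#'
#' Breadth-first search upward from every non-obsolete term over is_a
#' edges.  A row (subject, object, distance) is present iff a directed
#' is_a path of that length exists; the minimal distance is kept, and every
#' term gets a self-path at distance 0 so subsumption queries return
#' exact-type matches without special casing.
#'
#' @param graph an `so_graph`.
#' @return data.frame(subject, object, relationship = "is_a", distance).
#' @export
so_is_a_closure <- function(graph) {
  live <- graph$terms$accession[!graph$terms$obsolete]
  obs <- graph$terms$accession[graph$terms$obsolete]
  edges <- graph$is_a[graph$is_a$child %in% live & graph$is_a$parent %in% live, ]
  adj <- split(edges$parent, edges$child)
  rows <- vector("list", length(live))
  for (i in seq_along(live)) {
    s <- live[i]
    dist <- c(stats::setNames(0L, s))
    frontier <- s
    d <- 0L
    while (length(frontier)) {
      d <- d + 1L
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[!(nxt %in% names(dist))]
      if (length(nxt)) dist[nxt] <- d
      frontier <- nxt
    }
    rows[[i]] <- data.frame(subject = s, object = names(dist),
                            relationship = "is_a",
                            distance = unname(dist), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' All descendants of a term under the is_a closure
#'
#' Includes the term itself (the distance-0 self path), so a subsumption
#' query for "gene" also retrieves e.g. "mitochondrial gene".
#'
#' @param term accession of the query term.
#' @param closure closure data.frame from [so_is_a_closure()].
#' @return character vector of accessions.
#' @export
so_descendants <- function(term, closure) {
  if (!(term %in% closure$object))
    stop("unknown term in closure: ", term)
  unique(closure$subject[closure$object == term])
}

#' Admissible relationship triples entailed by the ontology
#'
#' A triple (C, R, T) is admissible iff there is a directed path from C to
#' T over is_a edges (upward) and R edges containing at least one R edge —
#' i.e. C is entailed to stand in R to T under subject-side is_a
#' inheritance, object-side upward is_a propagation, and R-transitivity.
#' Each triple is certified by a witness path emitted alongside it.
#'
#' @param graph an `so_graph`.
#' @param relationship one of the graph's relationship edge types
#'   (part_of, member_of, derives_from).
#' @return data.frame(subject_type, relationship, object_type, witness);
#'   witness is a human-readable path like `a -is_a-> b -part_of-> c`.
#' @export
so_admissible_triples <- function(graph, relationship) {
  if (!(relationship %in% c("part_of", "member_of", "derives_from")))
    stop("unknown relationship name: ", relationship)
  live <- graph$terms$accession[!graph$terms$obsolete]
  isa <- graph$is_a[graph$is_a$child %in% live & graph$is_a$parent %in% live, ]
  rels <- graph$rel[graph$rel$relationship == relationship &
                    graph$rel$subject %in% live & graph$rel$object %in% live, ]
  if (nrow(rels) == 0L)
    return(data.frame(subject_type = character(0), relationship = character(0),
                      object_type = character(0), witness = character(0)))
  adj_isa <- split(isa$parent, isa$child)
  adj_rel <- split(rels$object, rels$subject)
  out <- list()
  for (s in live) {
    # BFS over states (node, used_R); parent pointers give the witness path
    state0 <- paste0(s, "|0")
    parent <- stats::setNames(list(NULL), state0)
    queue <- state0
    while (length(queue)) {
      st <- queue[1]; queue <- queue[-1]
      node <- sub("\\|.$", "", st)
      used <- endsWith(st, "1")
      step <- function(nbrs, flag, label) {
        for (w in nbrs) {
          nst <- paste0(w, "|", if (flag) "1" else "0")
          if (!(nst %in% names(parent))) {
            parent[[nst]] <<- c(st, label)
            queue <<- c(queue, nst)
          }
        }
      }
      step(adj_isa[[node]] %||% character(0), used, "is_a")
      step(adj_rel[[node]] %||% character(0), TRUE, relationship)
    }
    reached <- names(parent)[endsWith(names(parent), "1")]
    for (st in reached) {
      t_ <- sub("\\|.$", "", st)
      # reconstruct witness
      path <- character(0)
      cur <- st
      while (!is.null(parent[[cur]])) {
        prev <- parent[[cur]]
        path <- c(paste0("-", prev[2], "-> ", sub("\\|.$", "", cur)), path)
        cur <- prev[1]
      }
      out[[length(out) + 1L]] <- data.frame(
        subject_type = s, relationship = relationship, object_type = t_,
        witness = paste(c(s, path), collapse = " "), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compute admissible triples for all three feature relationships
#'
#' The returned frame additionally carries a `fillers` attribute: per
#' relationship, the (subject_type, filler) pairs where the filler is the
#' target of the final R edge on an entailment path — the restriction
#' filler the subject is entailed to stand in R to.  The runtime
#' admissibility check ([so_relationship_allowed()]) compares concrete
#' object types against fillers, not against the upward-propagated triple
#' objects, so that e.g. an exon may attach to an mRNA (filler transcript
#' subsumes mRNA) while an mRNA may not derive from a gene (filler
#' primary_transcript is is_a-incomparable with gene).
#'
#' @param graph an `so_graph`.
#' @return one data.frame rbind-ing [so_admissible_triples()] for part_of,
#'   member_of and derives_from, with the `fillers` attribute described
#'   above.
#' @export
so_all_admissible_triples <- function(graph) {
  out <- do.call(rbind, lapply(c("part_of", "member_of", "derives_from"),
                               function(r) so_admissible_triples(graph, r)))
  attr(out, "fillers") <- so_admissible_fillers(graph)
  out
}

# (subject_type, relationship, filler) rows: filler = target of the last R
# edge on any entailment path from the subject
so_admissible_fillers <- function(graph) {
  live <- graph$terms$accession[!graph$terms$obsolete]
  isa <- graph$is_a[graph$is_a$child %in% live & graph$is_a$parent %in% live, ]
  adj_isa <- split(isa$parent, isa$child)
  out <- list()
  for (R in c("part_of", "member_of", "derives_from")) {
    rels <- graph$rel[graph$rel$relationship == R &
                      graph$rel$subject %in% live &
                      graph$rel$object %in% live, ]
    if (nrow(rels) == 0L) next
    adj_rel <- split(rels$object, rels$subject)
    for (s in live) {
      reach <- s
      frontier <- s
      while (length(frontier)) {
        nxt <- unique(unlist(c(adj_isa[frontier], adj_rel[frontier]),
                             use.names = FALSE))
        nxt <- nxt[!(nxt %in% reach)]
        reach <- c(reach, nxt)
        frontier <- nxt
      }
      fillers <- unique(unlist(adj_rel[reach], use.names = FALSE))
      if (length(fillers))
        out[[length(out) + 1L]] <- data.frame(
          subject_type = s, relationship = R, filler = fillers,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(subject_type = character(0), relationship = character(0),
                  filler = character(0))
}

#' Runtime admissibility check for a concrete feature pair
#'
#' Accepts (Tf, R, Tg) when the ontology entails Tf to stand in R to a
#' restriction filler T' that is is_a-comparable with Tg (Tg a
#' descendant-or-self of T', or an ancestor of T').  Generalizing the
#' filler over the object's is_a neighbourhood is what lets an exon
#' instance attach to an mRNA instance when the ontology asserts exon
#' part_of transcript, without admitting pairs whose only connection runs
#' through the hierarchy root.
#'
#' @param triples data.frame from [so_all_admissible_triples()] (must carry
#'   its `fillers` attribute).
#' @param closure data.frame from [so_is_a_closure()].
#' @param subject_type,relationship,object_type the concrete combination.
#' @return TRUE or FALSE.
#' @export
so_relationship_allowed <- function(triples, closure, subject_type,
                                    relationship, object_type) {
  fillers <- attr(triples, "fillers")
  if (is.null(fillers))
    stop("admissible triples lack the fillers attribute; ",
         "use so_all_admissible_triples()")
  f <- fillers$filler[fillers$subject_type == subject_type &
                      fillers$relationship == relationship]
  if (length(f) == 0L) return(FALSE)
  anc <- unique(closure$object[closure$subject == object_type])
  desc <- unique(closure$subject[closure$object == object_type])
  any(f %in% c(anc, desc, object_type))
}

#' Bundled feature-key to SO-term mapping (FTv8 snapshot)
#'
#' @param path optional override; defaults to the bundled tab-separated
#'   resource covering the 60 FTv8 feature keys.
#' @return data.frame(feature_key, so_accession, so_name).
#' @export
gb_feature_key_mapping <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "feature_key_so_mapping.tsv",
                        package = "gbloadr", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
}

#' Bundled qualifier routing table (FTv8 snapshot)
#'
#' Routes each of the 96 FTv8 qualifiers to one of: a feature annotation
#' typed by an ontology (or local) term, a Collection-table column, a
#' Taxonomy-table column, or suppression.
#'
#' @param path optional override; defaults to the bundled resource.
#' @return data.frame(qualifier, route, target).
#' @export
gb_qualifier_routing <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "qualifier_routing.tsv",
                        package = "gbloadr", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
}

#' Map a feature key to its ontology term
#'
#' Total function: keys present in the bundled mapping give their SO
#' accession; unknown keys fall back deterministically to a reserved local
#' namespace term `local:<key>`, mirroring the fallback to qualifier or
#' header-field names for concepts absent from the SO.
#'
#' @param key feature key text.
#' @param mapping data.frame from [gb_feature_key_mapping()].
#' @return a term accession (character).
#' @export
so_map_feature_key <- function(key, mapping = gb_feature_key_mapping()) {
  hit <- mapping$so_accession[mapping$feature_key == key]
  if (length(hit)) hit[1] else paste0("local:", key)
}
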