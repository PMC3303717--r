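#' @title Forward-chaining rule engine: facts, inference, statements
#' @description Converts parsed entries into template facts (header,
#'   sequence, key, portion, qualifier, reference, reference_portion),
#'   runs deterministic stratified inference phases (feature
#'   relationships, bibliographic evidence, implicit introns, qualifier
#'   routing) and emits an ordered list of insert/select statement facts
#'   with symbolic foreign keys.  Evaluation is stratified, so the same
#'   entry and ontology snapshot always produce the identical statement
#'   list.
#' @name rule-engine
NULL

#' Serialize a parsed entry into template facts
#'
#' One header fact, one sequence fact (length and presence only — residues
#' are deliberately excluded so the reasoner is never loaded with them),
#' one key fact per feature with its mapped ontology term, one portion fact
#' per location portion, one qualifier fact per qualifier, and one
#' reference plus one reference_portion fact per reference and cited range.
#'
#' @param entry a `gb_entry` from [gb_parse_entry()].
#' @param mapping feature-key mapping from [gb_feature_key_mapping()].
#' @return an object of class `gb_facts`.
#' @export
entry_facts <- function(entry, mapping = gb_feature_key_mapping()) {
  H <- entry$header
  feats <- entry$features
  nf <- length(feats)
  keys <- if (nf) data.frame(
    feature_id = seq_len(nf),
    key = vapply(feats, `[[`, character(1), "key"),
    term = vapply(feats, function(f) so_map_feature_key(f$key, mapping),
                  character(1)),
    rank = vapply(feats, `[[`, integer(1), "rank"),
    stringsAsFactors = FALSE)
  else data.frame(feature_id = integer(0), key = character(0),
                  term = character(0), rank = integer(0))
  empty_portions <- data.frame(
    feature_id = integer(0), start = integer(0), end = integer(0),
    strand = character(0), partial5 = logical(0), partial3 = logical(0),
    between_bases = logical(0), remote_accession = character(0),
    rank = integer(0))
  portions <- do.call(rbind, c(list(empty_portions),
    lapply(seq_len(nf), function(i) {
      p <- feats[[i]]$portions
      cbind(data.frame(feature_id = rep(i, nrow(p))), p)
    })))
  quals <- do.call(rbind, c(
    list(data.frame(feature_id = integer(0), name = character(0),
                    value = character(0))),
    lapply(seq_len(nf), function(i) {
      q <- feats[[i]]$qualifiers
      if (is.data.frame(q)) {
        if (nrow(q) == 0L) return(NULL)
        data.frame(feature_id = i, name = q$name, value = q$value,
                   stringsAsFactors = FALSE)
      } else {
        if (length(q) == 0L) return(NULL)
        data.frame(feature_id = i, name = names(q),
                   value = vapply(q, function(v)
                     if (is.na(v)) NA_character_ else as.character(v),
                     character(1)),
                   stringsAsFactors = FALSE)
      }
    })))
  refs <- do.call(rbind, c(
    list(data.frame(ordinal = integer(0), authors = character(0),
                    title = character(0), journal = character(0),
                    pubmed_id = integer(0))),
    lapply(entry$references, function(r)
      data.frame(ordinal = r$ordinal, authors = r$authors, title = r$title,
                 journal = r$journal, pubmed_id = r$pubmed_id,
                 stringsAsFactors = FALSE))))
  ref_portions <- do.call(rbind, c(
    list(data.frame(ordinal = integer(0), start = integer(0), end = integer(0))),
    lapply(entry$references, function(r) {
      cr <- r$cited_ranges
      if (nrow(cr) == 0L) return(NULL)
      data.frame(ordinal = r$ordinal, start = cr$start, end = cr$end)
    })))
  structure(list(
    header = H,
    sequence = list(length = H$sequence_length,
                    present = nzchar(entry$sequence)),
    keys = keys, portions = portions, qualifiers = quals,
    references = refs, reference_portions = ref_portions),
    class = "gb_facts")
}

#' Count the facts of an entry (header + sequence + key/portion/qualifier +
#' reference/reference_portion templates)
#' @param facts a `gb_facts` object.
#' @return integer fact count.
#' @export
n_facts <- function(facts) {
  1L + (if (facts$sequence$present) 1L else 0L) +
    nrow(facts$keys) + nrow(facts$portions) + nrow(facts$qualifiers) +
    nrow(facts$references) + nrow(facts$reference_portions)
}

# span of each feature over its non-remote portions: [min start, max end]
# envelope, covered base count, and strand (NA when portions mix strands,
# treated as strandless)
feature_spans <- function(facts) {
  ids <- facts$keys$feature_id
  out <- data.frame(feature_id = ids,
                    start = rep(NA_integer_, length(ids)),
                    end = rep(NA_integer_, length(ids)),
                    coverage = rep(NA_integer_, length(ids)),
                    strand = rep(NA_character_, length(ids)),
                    has_local = rep(FALSE, length(ids)))
  for (i in seq_along(ids)) {
    p <- facts$portions[facts$portions$feature_id == ids[i] &
                        is.na(facts$portions$remote_accession), , drop = FALSE]
    if (nrow(p) == 0L) next
    out$start[i] <- min(p$start)
    out$end[i] <- max(p$end)
    out$coverage[i] <- sum(p$end - p$start + 1L)
    s <- unique(p$strand)
    out$strand[i] <- if (length(s) == 1L) s else NA_character_
    out$has_local[i] <- TRUE
  }
  out
}

qual_values <- function(facts, id, name) {
  v <- facts$qualifiers$value[facts$qualifiers$feature_id == id &
                              facts$qualifiers$name == name]
  v[!is.na(v)]
}

# D20 qualifier consistency between candidate subject f and object g
qualifier_consistent <- function(facts, f, g, relationship) {
  keys <- c("locus_tag", "gene")
  if (relationship == "derives_from") {
    pf <- qual_values(facts, f, "protein_id")
    pg <- qual_values(facts, g, "protein_id")
    if (length(intersect(pf, pg))) return(TRUE)
    keys <- c(keys, "protein_id")
  }
  any_carried <- FALSE
  for (k in keys) {
    vf <- qual_values(facts, f, k)
    vg <- qual_values(facts, g, k)
    if (length(vf) || length(vg)) any_carried <- TRUE
    if (length(intersect(vf, vg))) return(TRUE)
  }
  !any_carried  # neither feature carries any: location alone decides
}

# D21 location coherence: span containment on the same strand; features
# with mixed-strand portions are containment-checked ignoring strand
location_coherent <- function(spans, f, g) {
  sf <- spans[spans$feature_id == f, ]
  sg <- spans[spans$feature_id == g, ]
  if (!sf$has_local || !sg$has_local) return(FALSE)
  if (!is.na(sf$strand) && !is.na(sg$strand) && sf$strand != sg$strand)
    return(FALSE)
  sf$start >= sg$start && sf$end <= sg$end
}

#' Infer part_of / member_of / derives_from relationships among features
#'
#' A feature f is related to g by R iff (i) the concrete type pair is
#' admissible — an admissible triple (type(f), R, A) exists for type(g) or
#' one of its is_a ancestors; (ii) f and g are qualifier-consistent: they
#' share a value of /locus_tag or /gene (an identical /protein_id suffices
#' for derives_from), or neither carries any of those qualifiers; and
#' (iii) f's span is contained in g's span on the same strand.  Among
#' multiple qualifying parents for the same R, only the minimal-span one is
#' kept; remaining ties go to the earliest feature in entry order.
#'
#' @param facts a `gb_facts` object.
#' @param triples admissible triples from [so_all_admissible_triples()].
#' @param closure is_a closure from [so_is_a_closure()].
#' @return data.frame(subject, relationship, object, provenance).
#' @export
infer_relationships <- function(facts, triples, closure) {
  empty <- data.frame(subject = integer(0), relationship = character(0),
                      object = integer(0), provenance = character(0))
  n <- nrow(facts$keys)
  if (n < 2L) return(empty)
  spans <- feature_spans(facts)
  out <- empty
  for (R in c("part_of", "member_of", "derives_from")) {
    for (f in facts$keys$feature_id) {
      tf <- facts$keys$term[f]
      candidates <- integer(0)
      for (g in facts$keys$feature_id) {
        if (f == g) next
        tg <- facts$keys$term[g]
        if (!so_relationship_allowed(triples, closure, tf, R, tg)) next
        if (!qualifier_consistent(facts, f, g, R)) next
        if (!location_coherent(spans, f, g)) next
        candidates <- c(candidates, g)
      }
      if (length(candidates) == 0L) next
      # minimal parent = fewest covered bases (a spliced transcript is
      # smaller than its gene even when their envelopes coincide); ties go
      # to entry order
      best <- candidates[order(spans$coverage[candidates],
                               facts$keys$rank[candidates])][1]
      shared <- {
        ks <- c("locus_tag", "gene", if (R == "derives_from") "protein_id")
        hit <- ks[vapply(ks, function(k)
          length(intersect(qual_values(facts, f, k),
                           qual_values(facts, best, k))) > 0, logical(1))]
        if (length(hit)) paste0("qualifier:", hit[1]) else "location-only"
      }
      out <- rbind(out, data.frame(
        subject = f, relationship = R, object = best,
        provenance = paste0(shared, ";span-containment"),
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Link features to their bibliographic evidence
#'
#' FTv8 references cite specific base ranges; a feature is linked to a
#' reference iff the feature's span is contained in one of the reference's
#' cited ranges (location coherence, containment form).
#'
#' @param facts a `gb_facts` object.
#' @return data.frame(feature_id, ordinal).
#' @export
assign_reference_evidence <- function(facts) {
  out <- data.frame(feature_id = integer(0), ordinal = integer(0))
  if (nrow(facts$reference_portions) == 0L || nrow(facts$keys) == 0L)
    return(out)
  spans <- feature_spans(facts)
  for (f in facts$keys$feature_id) {
    sf <- spans[spans$feature_id == f, ]
    if (!sf$has_local) next
    rp <- facts$reference_portions
    hit <- unique(rp$ordinal[sf$start >= rp$start & sf$end <= rp$end])
    if (length(hit))
      out <- rbind(out, data.frame(feature_id = f, ordinal = hit))
  }
  rownames(out) <- NULL
  out
}

#' Default intron-donor term list: transcript-class terms and CDS
#' @export
intron_donor_terms <- function() c("SO:0000673", "SO:0000316")

#' Compute implicit introns from multi-portion donor features
#'
#' The intron feature key is not present in all entries, but where
#' conceptually feasible intron locations can be computed: for every
#' feature whose type is (via the is_a closure) a transcript-class term or
#' CDS and which has two or more non-remote portions on one strand, each
#' inter-portion gap (e1+1, s2-1) becomes an implicit intron carrying the
#' donor's strand, typed with the SO intron term and related part_of to the
#' donor.  An explicit intron feature with identical coordinates
#' suppresses the inferred one.
#'
#' @param facts a `gb_facts` object.
#' @param closure is_a closure.
#' @param donor_terms term accessions whose descendants qualify as donors.
#' @return list(features = data.frame(feature_id, donor_feature_id, start,
#'   end, strand, rank), relationships = data.frame(subject, relationship,
#'   object, provenance)); feature ids continue the entry's numbering.
#' @export
infer_introns <- function(facts, closure,
                          donor_terms = intron_donor_terms()) {
  ancestors <- split(closure$object, closure$subject)
  intron_acc <- "SO:0000188"
  explicit <- local({
    ids <- facts$keys$feature_id[vapply(facts$keys$term, function(t)
      intron_acc %in% (ancestors[[t]] %||% t), logical(1))]
    if (length(ids) == 0L) return(data.frame(start = integer(0), end = integer(0)))
    p <- facts$portions[facts$portions$feature_id %in% ids, , drop = FALSE]
    p[, c("start", "end")]
  })
  feats <- NULL
  rels <- data.frame(subject = integer(0), relationship = character(0),
                     object = integer(0), provenance = character(0))
  next_id <- if (nrow(facts$keys)) max(facts$keys$feature_id) + 1L else 1L
  next_rank <- if (nrow(facts$keys)) max(facts$keys$rank) + 1L else 0L
  for (i in seq_len(nrow(facts$keys))) {
    term <- facts$keys$term[i]
    if (!any(donor_terms %in% (ancestors[[term]] %||% term))) next
    p <- facts$portions[facts$portions$feature_id == facts$keys$feature_id[i] &
                        is.na(facts$portions$remote_accession), , drop = FALSE]
    if (nrow(p) < 2L || length(unique(p$strand)) != 1L) next
    p <- p[order(p$start), ]
    for (j in seq_len(nrow(p) - 1L)) {
      s <- p$end[j] + 1L
      e <- p$start[j + 1L] - 1L
      if (e < s) next
      if (any(explicit$start == s & explicit$end == e)) next
      feats <- rbind(feats, data.frame(
        feature_id = next_id, donor_feature_id = facts$keys$feature_id[i],
        start = s, end = e, strand = p$strand[1], rank = next_rank))
      rels <- rbind(rels, data.frame(
        subject = next_id, relationship = "part_of",
        object = facts$keys$feature_id[i],
        provenance = "implicit-intron;portion-gap", stringsAsFactors = FALSE))
      next_id <- next_id + 1L
      next_rank <- next_rank + 1L
    }
  }
  list(features = feats %||% data.frame(
         feature_id = integer(0), donor_feature_id = integer(0),
         start = integer(0), end = integer(0), strand = character(0),
         rank = integer(0)),
       relationships = rels)
}

#' Route qualifiers to annotation, Collection or Taxonomy bindings
#'
#' Collection-routed qualifiers (country, lat_lon, collection_date,
#' specimen_voucher, isolation_source, ...) produce Collection-table column
#' bindings; taxonomy-routed qualifiers (organism; db_xref values of the
#' form `taxon:<id>`) produce Taxonomy bindings; suppressed qualifiers are
#' dropped; everything else — including qualifiers unknown to the routing
#' table — becomes a feature annotation typed by an ontology or local term.
#'
#' @param facts a `gb_facts` object.
#' @param routing routing table from [gb_qualifier_routing()].
#' @return list(annotation, collection, taxonomy) data.frames.
#' @export
route_qualifiers <- function(facts, routing = gb_qualifier_routing()) {
  ann <- data.frame(feature_id = integer(0), term = character(0),
                    qualifier = character(0), value = character(0))
  coll <- data.frame(column = character(0), value = character(0))
  taxo <- data.frame(column = character(0), value = character(0))
  H <- facts$header
  if (nzchar(H$organism_name))
    taxo <- rbind(taxo, data.frame(column = "organismName",
                                   value = H$organism_name))
  if (length(H$lineage))
    taxo <- rbind(taxo, data.frame(column = "lineage",
                                   value = paste(H$lineage, collapse = "; ")))
  q <- facts$qualifiers
  for (i in seq_len(nrow(q))) {
    name <- q$name[i]
    value <- if (is.na(q$value[i])) "" else q$value[i]
    r <- routing[routing$qualifier == name, , drop = FALSE]
    route <- if (nrow(r)) r$route[1] else "annotation"
    target <- if (nrow(r)) r$target[1] else paste0("local:", name)
    if (route == "suppressed") next
    if (route == "taxonomy") {
      if (name == "db_xref") {
        m <- regmatches(value, regexec("^taxon:(\\d+)$", value))[[1]]
        if (length(m) == 2L) {
          taxo <- rbind(taxo, data.frame(column = "ncbiTaxonId", value = m[2]))
        } else {
          ann <- rbind(ann, data.frame(feature_id = q$feature_id[i],
                                       term = "local:db_xref",
                                       qualifier = name, value = value))
        }
      } else {
        taxo <- rbind(taxo, data.frame(column = target, value = value))
      }
    } else if (route == "collection") {
      coll <- rbind(coll, data.frame(column = target, value = value))
    } else {
      ann <- rbind(ann, data.frame(feature_id = q$feature_id[i], term = target,
                                   qualifier = name, value = value))
    }
  }
  coll <- coll[!duplicated(coll$column), , drop = FALSE]
  taxo <- taxo[!duplicated(taxo$column), , drop = FALSE]
  rownames(ann) <- rownames(coll) <- rownames(taxo) <- NULL
  list(annotation = ann, collection = coll, taxonomy = taxo)
}

new_statement <- function(kind, count, table, columns, values,
                          foreign_counts = integer(0),
                          foreign_columns = character(0)) {
  list(kind = kind, count = count, table = table, columns = columns,
       values = values, foreign_counts = foreign_counts,
       foreign_columns = foreign_columns)
}

#' Validate the internal consistency of a statement list
#'
#' Counts must be strictly increasing and every foreign count must cite an
#' earlier statement of the same list (so the cited insert always precedes
#' the citing one and cycles are impossible).
#'
#' @param statements list of statement facts.
#' @return invisibly TRUE; errors on violation.
#' @export
validate_statements <- function(statements) {
  counts <- vapply(statements, `[[`, numeric(1), "count")
  if (any(diff(counts) <= 0))
    stop("statement generation error: counts are not strictly increasing")
  seen <- numeric(0)
  for (s in statements) {
    if (length(s$foreign_counts) != length(s$foreign_columns))
      stop("statement generation error: foreign counts/columns misaligned in count ",
           s$count)
    for (fc in s$foreign_counts)
      if (!(fc %in% seen))
        stop("statement generation error: dangling foreign count ", fc,
             " cited by statement ", s$count)
    if (!all(s$foreign_columns %in% s$columns))
      stop("statement generation error: foreign column absent from columns in count ",
           s$count)
    seen <- c(seen, s$count)
  }
  invisible(TRUE)
}

term_name_for <- function(acc, mapping) {
  hit <- mapping$so_name[mapping$so_accession == acc]
  if (length(hit)) hit[1]
  else if (startsWith(acc, "local:")) sub("^local:", "", acc)
  else acc
}

#' Generate the ordered insert/select statement list for one entry
#'
#' Transforms the facts and all derived facts of one entry into an ordered
#' set of statements.  Each statement carries a `count` identifier; a later
#' insert cites an earlier one through its `foreign_counts`, and at
#' execution time the cited statement's database-generated primary key is
#' substituted into the aligned foreign column.  Parent inserts always
#' precede the inserts that cite them.
#'
#' @param facts `gb_facts` for the entry.
#' @param relationships from [infer_relationships()].
#' @param evidences from [assign_reference_evidence()].
#' @param introns from [infer_introns()].
#' @param routed from [route_qualifiers()].
#' @param mapping feature-key mapping (for term names).
#' @return list of statement facts, validated by [validate_statements()].
#' @export
build_statements <- function(facts, relationships, evidences, introns, routed,
                             mapping = gb_feature_key_mapping()) {
  H <- facts$header
  stmts <- list()
  cnt <- 0L
  push <- function(kind, table, columns, values, fc = integer(0),
                   fcol = character(0)) {
    cnt <<- cnt + 1L
    stmts[[cnt]] <<- new_statement(kind, cnt, table, columns, values, fc, fcol)
    cnt
  }
  tax <- routed$taxonomy
  c_tax <- push("select", "taxonomy", tax$column, as.list(tax$value))
  c_ind <- NULL
  if (nrow(routed$collection)) {
    c_ind <- push("insert", "individual", "identificationId", list(NA),
                  fc = c_tax, fcol = "identificationId")
    push("insert", "collection_event",
         c("individualId", routed$collection$column),
         c(list(NA), as.list(routed$collection$value)),
         fc = c_ind, fcol = "individualId")
  }
  entry_cols <- c("gi", "accession", "version", "locusName", "definition",
                  "sequenceLength", "moleculeType", "topology", "divisionCode",
                  "modificationDate", "keywords", "taxonomyId")
  entry_vals <- list(H$gi, H$accession, H$version, H$locus_name, H$definition,
                     H$sequence_length, H$molecule_type, H$topology,
                     H$division_code, H$modification_date,
                     paste(H$keywords, collapse = "; "), NA)
  fc <- c_tax; fcol <- "taxonomyId"
  if (!is.null(c_ind)) {
    entry_cols <- c(entry_cols, "individualId")
    entry_vals <- c(entry_vals, list(NA))
    fc <- c(fc, c_ind); fcol <- c(fcol, "individualId")
  }
  c_entry <- push("insert", "entry", entry_cols, entry_vals, fc, fcol)
  push("insert", "sequence", c("entryId", "length"),
       list(NA, facts$sequence$length), fc = c_entry, fcol = "entryId")
  # ontology term selects (get-or-create): feature types, annotation types,
  # relationship types
  all_rels <- rbind(relationships, introns$relationships)
  terms_used <- unique(c(
    facts$keys$term,
    if (nrow(introns$features)) "SO:0000188",
    routed$annotation$term,
    if (nrow(all_rels)) paste0("local:", unique(all_rels$relationship))))
  c_terms <- stats::setNames(integer(0), character(0))
  for (t in terms_used) {
    c_terms[[t]] <- push("select", "ontology_term", c("accession", "name"),
                         list(t, term_name_for(t, mapping)))
  }
  # sequence features: entry features then implicit introns
  spans <- feature_spans(facts)
  c_feat <- stats::setNames(integer(0), character(0))
  for (i in seq_len(nrow(facts$keys))) {
    id <- facts$keys$feature_id[i]
    sp <- spans[spans$feature_id == id, ]
    c_feat[[as.character(id)]] <- push(
      "insert", "sequence_feature",
      c("entryId", "typeTermId", "rank", "spanStart", "spanEnd", "strand",
        "featureKey"),
      list(NA, NA, facts$keys$rank[i],
           if (sp$has_local) sp$start else NA,
           if (sp$has_local) sp$end else NA,
           if (sp$has_local) sp$strand else NA,
           facts$keys$key[i]),
      fc = c(c_entry, c_terms[[facts$keys$term[i]]]),
      fcol = c("entryId", "typeTermId"))
    p <- facts$portions[facts$portions$feature_id == id, , drop = FALSE]
    for (j in seq_len(nrow(p)))
      push("insert", "feature_portion",
           c("featureId", "start", "end", "strand", "partial5", "partial3",
             "betweenBases", "remoteAccession", "rank"),
           list(NA, p$start[j], p$end[j], p$strand[j],
                as.integer(p$partial5[j]), as.integer(p$partial3[j]),
                as.integer(p$between_bases[j]), p$remote_accession[j],
                p$rank[j]),
           fc = c_feat[[as.character(id)]], fcol = "featureId")
  }
  for (i in seq_len(nrow(introns$features))) {
    it <- introns$features[i, ]
    c_feat[[as.character(it$feature_id)]] <- push(
      "insert", "sequence_feature",
      c("entryId", "typeTermId", "rank", "spanStart", "spanEnd", "strand",
        "featureKey"),
      list(NA, NA, it$rank, it$start, it$end, it$strand, "intron"),
      fc = c(c_entry, c_terms[["SO:0000188"]]),
      fcol = c("entryId", "typeTermId"))
    push("insert", "feature_portion",
         c("featureId", "start", "end", "strand", "partial5", "partial3",
           "betweenBases", "remoteAccession", "rank"),
         list(NA, it$start, it$end, it$strand, 0L, 0L, 0L, NA_character_, 0L),
         fc = c_feat[[as.character(it$feature_id)]], fcol = "featureId")
  }
  for (i in seq_len(nrow(routed$annotation))) {
    a <- routed$annotation[i, ]
    push("insert", "feature_annotation",
         c("featureId", "typeTermId", "qualifier", "value"),
         list(NA, NA, a$qualifier, a$value),
         fc = c(c_feat[[as.character(a$feature_id)]], c_terms[[a$term]]),
         fcol = c("featureId", "typeTermId"))
  }
  c_ref <- stats::setNames(integer(0), character(0))
  for (i in seq_len(nrow(facts$references))) {
    r <- facts$references[i, ]
    rp <- facts$reference_portions[facts$reference_portions$ordinal ==
                                   r$ordinal, , drop = FALSE]
    c_ref[[as.character(r$ordinal)]] <- push(
      "insert", "reference",
      c("entryId", "ordinal", "authors", "title", "journal", "pubmedId",
        "citedRanges"),
      list(NA, r$ordinal, r$authors, r$title, r$journal, r$pubmed_id,
           paste(sprintf("%d..%d", rp$start, rp$end), collapse = ";")),
      fc = c_entry, fcol = "entryId")
  }
  for (i in seq_len(nrow(evidences))) {
    e <- evidences[i, ]
    push("insert", "reference_evidence", c("featureId", "referenceId"),
         list(NA, NA),
         fc = c(c_feat[[as.character(e$feature_id)]],
                c_ref[[as.character(e$ordinal)]]),
         fcol = c("featureId", "referenceId"))
  }
  for (i in seq_len(nrow(all_rels))) {
    r <- all_rels[i, ]
    push("insert", "feature_relationship",
         c("subjectId", "objectId", "relTypeTermId", "provenance"),
         list(NA, NA, NA, r$provenance),
         fc = c(c_feat[[as.character(r$subject)]],
                c_feat[[as.character(r$object)]],
                c_terms[[paste0("local:", r$relationship)]]),
         fcol = c("subjectId", "objectId", "relTypeTermId"))
  }
  validate_statements(stmts)
  stmts
}

#' Run the full stratified rule pipeline for one entry
#'
#' Phases in order: facts, relationships, reference evidence, implicit
#' introns, qualifier routing, statement generation.
#'
#' @param entry a `gb_entry`.
#' @param setup a setup object from [run_setup()] (closure, triples,
#'   mapping, routing, donor terms).
#' @return list(facts, relationships, evidences, introns, routed,
#'   statements).
#' @export
reason_entry <- function(entry, setup) {
  facts <- entry_facts(entry, setup$mapping)
  relationships <- infer_relationships(facts, setup$triples, setup$closure)
  evidences <- assign_reference_evidence(facts)
  introns <- infer_introns(facts, setup$closure, setup$donor_terms)
  routed <- route_qualifiers(facts, setup$routing)
  statements <- build_statements(facts, relationships, evidences, introns,
                                 routed, setup$mapping)
  list(facts = facts, relationships = relationships, evidences = evidences,
       introns = introns, routed = routed, statements = statements)
}
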