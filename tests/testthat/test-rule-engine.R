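# rule engine: fact serialization, relationship inference, reference
# evidence, implicit introns, qualifier routing, statement generation

test_that("an entry serializes into the expected fact multiset", {
  # 2 features (1 portion, 2 qualifiers each) + 1 reference with 1 range:
  # 1 header + 1 sequence + 2 key + 2 portion + 4 qualifier + 1 reference
  # + 1 reference_portion = 12 facts
  e <- parse_hand_entry(list(
    list(key = "gene", portions = pr(10, 200),
         qualifiers = list(gene = "abcA", locus_tag = "T1")),
    list(key = "misc_feature", portions = pr(300, 400),
         qualifiers = list(note = "x", label = "y"))), len = 500L)
  f <- entry_facts(e, mini()$mapping)
  expect_equal(n_facts(f), 12L)
  expect_equal(nrow(f$keys), 2L)
  expect_equal(f$keys$term, c("SO:0000704", "SO:0000001"))
  # entry with no references -> no reference facts
  e2 <- parse_hand_entry(list(list(key = "source", portions = pr(1, 100))),
                         len = 100L, with_reference = FALSE)
  f2 <- entry_facts(e2, mini()$mapping)
  expect_equal(nrow(f2$references), 0L)
  expect_equal(nrow(f2$reference_portions), 0L)
  # fixture entries match the manifest's expected count
  fx <- generate_entries(4, seed = 23, profile = "nested_gene_models")
  path <- tempfile()
  write_fixture(fx, path)
  entries <- gb_read_entries(path)
  for (i in seq_along(entries))
    expect_equal(n_facts(entry_facts(entries[[i]], mini()$mapping)),
                 fx$manifest[[i]]$expected_fact_count)
})

test_that("gene/mRNA/CDS with shared gene symbol resolve to the minimal parents", {
  m <- mini()
  e <- parse_hand_entry(list(
    list(key = "gene", portions = pr(1, 500),
         qualifiers = list(gene = "abcA")),
    list(key = "mRNA", portions = rbind(pr(1, 100), pr(201, 500)),
         qualifiers = list(gene = "abcA")),
    list(key = "CDS", portions = rbind(pr(10, 100), pr(201, 450)),
         qualifiers = list(gene = "abcA"))), len = 600L)
  rel <- infer_relationships(entry_facts(e, m$mapping), m$triples, m$closure)
  expect_setequal(edge_key(rel),
                  c("2 part_of 1", "3 part_of 2"))  # CDS under mRNA, not gene
  expect_match(rel$provenance[rel$subject == 3], "qualifier:gene")
})

test_that("disjoint genes with different symbols stay unrelated", {
  m <- mini()
  e <- parse_hand_entry(list(
    list(key = "gene", portions = pr(1, 200), qualifiers = list(gene = "aaa")),
    list(key = "gene", portions = pr(300, 500), qualifiers = list(gene = "bbb")),
    list(key = "mRNA", portions = pr(300, 480), qualifiers = list(gene = "bbb"))),
    len = 600L)
  rel <- infer_relationships(entry_facts(e, m$mapping), m$triples, m$closure)
  expect_equal(edge_key(rel), "3 part_of 2")
})

test_that("a shared protein_id licenses derives_from", {
  m <- mini()
  e <- parse_hand_entry(list(
    list(key = "CDS", portions = pr(10, 400),
         qualifiers = list(protein_id = "AAA1.1")),
    list(key = "mat_peptide", portions = pr(40, 200),
         qualifiers = list(protein_id = "AAA1.1"))), len = 500L)
  rel <- infer_relationships(entry_facts(e, m$mapping), m$triples, m$closure)
  df <- rel[rel$relationship == "derives_from", ]
  expect_equal(nrow(df), 1L)
  expect_equal(c(df$subject, df$object), c(2L, 1L))
  expect_match(df$provenance, "protein_id")
})

test_that("relationship inference is deterministic across runs", {
  m <- mini()
  fx <- generate_entries(3, seed = 29, profile = "nested_gene_models")
  path <- tempfile()
  write_fixture(fx, path)
  e <- gb_read_entries(path)[[1]]
  f <- entry_facts(e, m$mapping)
  r1 <- infer_relationships(f, m$triples, m$closure)
  r2 <- infer_relationships(f, m$triples, m$closure)
  expect_identical(r1, r2)
})

test_that("reference evidence attaches by containment in cited ranges", {
  mk <- function(feat_range, ref_end = 800L) {
    e <- parse_hand_entry(list(
      list(key = "gene", portions = pr(feat_range[1], feat_range[2]),
           qualifiers = list(gene = "g"))), len = 1000L,
      with_reference = FALSE)
    f <- entry_facts(e, mini()$mapping)
    f$references <- data.frame(ordinal = 1L, authors = "", title = "",
                               journal = "", pubmed_id = NA_integer_)
    f$reference_portions <- data.frame(ordinal = 1L, start = 1L, end = ref_end)
    f
  }
  expect_equal(assign_reference_evidence(mk(c(100, 400)))$feature_id, 1L)
  expect_equal(nrow(assign_reference_evidence(mk(c(700, 900)))), 0L)
  # whole-entry range links every feature
  f <- mk(c(700, 900), ref_end = 1000L)
  expect_equal(nrow(assign_reference_evidence(f)), 1L)
})

test_that("implicit introns tile the portion gaps with the donor's strand", {
  m <- mini()
  mk <- function(portions) {
    e <- parse_hand_entry(list(list(key = "mRNA", portions = portions,
                                    qualifiers = list(gene = "g"))),
                          len = 400L, with_reference = FALSE)
    infer_introns(entry_facts(e, m$mapping), m$closure)
  }
  it <- mk(rbind(pr(1, 100), pr(201, 300)))
  expect_equal(it$features$start, 101L)
  expect_equal(it$features$end, 200L)
  expect_equal(it$features$strand, "forward")
  expect_equal(edge_key(it$relationships), "2 part_of 1")
  expect_equal(nrow(mk(pr(1, 300))$features), 0L)
  rev <- mk(rbind(pr(1, 100, "reverse"), pr(201, 300, "reverse")))
  expect_equal(rev$features$strand, "reverse")
  expect_equal(c(rev$features$start, rev$features$end), c(101L, 200L))
})

test_that("an explicit intron with identical coordinates suppresses inference", {
  m <- mini()
  e <- parse_hand_entry(list(
    list(key = "mRNA", portions = rbind(pr(1, 100), pr(201, 300)),
         qualifiers = list(gene = "g")),
    list(key = "intron", portions = pr(101, 200),
         qualifiers = list(gene = "g"))), len = 400L, with_reference = FALSE)
  it <- infer_introns(entry_facts(e, m$mapping), m$closure)
  expect_equal(nrow(it$features), 0L)
})

test_that("inferred introns and portions exactly tile each donor's span", {
  m <- mini()
  fx <- generate_entries(10, seed = 31, profile = "nested_gene_models")
  path <- tempfile()
  write_fixture(fx, path)
  for (e in gb_read_entries(path)) {
    f <- entry_facts(e, m$mapping)
    it <- infer_introns(f, m$closure)
    for (donor in unique(it$features$donor_feature_id)) {
      p <- f$portions[f$portions$feature_id == donor, ]
      iv <- it$features[it$features$donor_feature_id == donor, ]
      segs <- rbind(p[, c("start", "end")], iv[, c("start", "end")])
      segs <- segs[order(segs$start), ]
      expect_true(all(segs$start[-1] == segs$end[-nrow(segs)] + 1L))
      expect_equal(segs$start[1], min(p$start))
      expect_equal(segs$end[nrow(segs)], max(p$end))
    }
  }
})

test_that("qualifiers route to collection, taxonomy, annotation or nowhere", {
  m <- mini()
  e <- parse_hand_entry(list(
    list(key = "source", portions = pr(1, 500),
         qualifiers = list(organism = "Testus testus", country = "Italy",
                           db_xref = "taxon:9606")),
    list(key = "CDS", portions = pr(10, 400),
         qualifiers = list(product = "VP35", frobnicate = "x",
                           translation = "MKV", germline = NA))),
    len = 500L, with_reference = FALSE)
  routed <- route_qualifiers(entry_facts(e, m$mapping), m$routing)
  expect_true(any(routed$collection$column == "country" &
                  routed$collection$value == "Italy"))
  expect_true(any(routed$taxonomy$column == "ncbiTaxonId" &
                  routed$taxonomy$value == "9606"))
  ann <- routed$annotation
  expect_true(any(ann$qualifier == "product" & ann$value == "VP35" &
                  ann$term == "local:product"))
  expect_true(any(ann$term == "local:frobnicate"))       # unknown fallback
  expect_false(any(ann$qualifier == "translation"))       # suppressed
  expect_true(any(ann$qualifier == "germline" & ann$value == ""))
})

test_that("statement lists are ordered, complete and validated", {
  m <- mini()
  # minimal entry: taxonomy select + entry + sequence inserts only
  e <- parse_hand_entry(list(), len = 120L, with_reference = FALSE)
  r <- reason_entry(e, list(mapping = m$mapping, routing = m$routing,
                            triples = m$triples, closure = m$closure,
                            donor_terms = m$donor_terms))
  expect_equal(vapply(r$statements, `[[`, character(1), "table"),
               c("taxonomy", "entry", "sequence"))
  expect_equal(vapply(r$statements, `[[`, character(1), "kind"),
               c("select", "insert", "insert"))
  # one feature + one qualifier: annotation insert cites the feature insert
  e2 <- parse_hand_entry(list(
    list(key = "CDS", portions = pr(10, 100),
         qualifiers = list(product = "p1"))), len = 200L,
    with_reference = FALSE)
  r2 <- reason_entry(e2, list(mapping = m$mapping, routing = m$routing,
                              triples = m$triples, closure = m$closure,
                              donor_terms = m$donor_terms))
  tabs <- vapply(r2$statements, `[[`, character(1), "table")
  k_feat <- r2$statements[[which(tabs == "sequence_feature")]]$count
  ann <- r2$statements[[which(tabs == "feature_annotation")]]
  expect_gt(ann$count, k_feat)
  expect_true(k_feat %in% ann$foreign_counts)
  counts <- vapply(r2$statements, `[[`, integer(1), "count")
  expect_true(all(diff(counts) > 0))
  # a dangling foreign count is rejected
  bad <- r2$statements
  i <- which(tabs == "feature_annotation")
  bad[[i]]$foreign_counts[1] <- 9999L
  expect_error(validate_statements(bad), "dangling foreign count")
})

test_that("reasoning an entry twice yields identical statement lists", {
  m <- mini()
  setup <- list(mapping = m$mapping, routing = m$routing, triples = m$triples,
                closure = m$closure, donor_terms = m$donor_terms)
  fx <- generate_entries(2, seed = 37, profile = "nested_gene_models")
  path <- tempfile()
  write_fixture(fx, path)
  e <- gb_read_entries(path)[[1]]
  expect_identical(reason_entry(e, setup)$statements,
                   reason_entry(e, setup)$statements)
})

test_that("every inferred relationship is admissible against the ontology", {
  m <- mini()
  fx <- generate_entries(6, seed = 41, profile = "nested_gene_models")
  path <- tempfile()
  write_fixture(fx, path)
  for (e in gb_read_entries(path)) {
    f <- entry_facts(e, m$mapping)
    rel <- infer_relationships(f, m$triples, m$closure)
    for (i in seq_len(nrow(rel))) {
      expect_true(so_relationship_allowed(
        m$triples, m$closure,
        f$keys$term[rel$subject[i]], rel$relationship[i],
        f$keys$term[rel$object[i]]))
      expect_true(rel$subject[i] != rel$object[i])
    }
  }
})
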