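# FTv8 parser: location grammar, section split, header/reference/feature
# parsing, indexing, and manifest round trips

test_that("location grammar covers ranges, complement, fuzzy, between, remote", {
  p <- gb_parse_location("340..565")
  expect_equal(p$start, 340L)
  expect_equal(p$end, 565L)
  expect_equal(p$strand, "forward")
  expect_false(any(p$partial5, p$partial3, p$between_bases))

  p <- gb_parse_location("complement(join(2691..4571,4918..5163))")
  expect_equal(p$start, c(2691L, 4918L))
  expect_equal(p$end, c(4571L, 5163L))
  expect_equal(p$strand, c("reverse", "reverse"))
  expect_equal(p$rank, c(0L, 1L))

  p <- gb_parse_location("<1..206")
  expect_equal(p$start, 1L)
  expect_true(p$partial5)
  expect_false(p$partial3)

  p <- gb_parse_location("1..>206")
  expect_true(p$partial3)

  p <- gb_parse_location("123^124")
  expect_equal(c(p$start, p$end), c(123L, 124L))
  expect_true(p$between_bases)

  p <- gb_parse_location("467")
  expect_equal(c(p$start, p$end), c(467L, 467L))

  p <- gb_parse_location("J00194.1:100..202")
  expect_equal(p$remote_accession, "J00194.1")

  p <- gb_parse_location("order(1..10,20..30)")
  expect_equal(attr(p, "location_operator"), "order")
  expect_equal(nrow(p), 2L)
})

test_that("malformed locations are rejected with the offending string", {
  expect_error(gb_parse_location("complement(complement(1..10))"),
               "nested complement")
  expect_error(gb_parse_location("join(1..10,20..30"), "unbalanced")
  expect_error(gb_parse_location("frobnicate(1..10)"), "1..10", fixed = TRUE)
  expect_error(gb_parse_location("10..5"), "start > end")
  expect_error(gb_parse_location("123^200"), "adjacent")
})

test_that("split_entry partitions every generated entry losslessly", {
  for (profile in c("minimal", "nested_gene_models", "reference_rich",
                    "adversarial")) {
    fx <- generate_entries(3, seed = 11, profile = profile)
    path <- tempfile()
    write_fixture(fx, path)
    idx <- gb_index_entries(path)
    for (off in idx$header_offset) {
      txt <- gb_read_entry_at(path, off)
      s <- gb_split_entry(txt)
      parts <- c(s$header_text, s$references_text, s$features_text,
                 s$sequence_text)
      expect_identical(paste(parts[nzchar(parts)], collapse = "\n"), txt)
    }
  }
})

test_that("split_entry localizes references and reports missing sections", {
  txt <- make_entry_text(list(list(key = "source", portions = pr(1, 100))),
                         len = 100L, with_reference = FALSE)
  s <- gb_split_entry(txt)
  expect_identical(s$references_text, "")
  expect_match(s$features_text, "FEATURES")
  txt2 <- make_entry_text(list(list(key = "source", portions = pr(1, 100))),
                          len = 100L)
  expect_equal(length(gregexpr("REFERENCE", gb_split_entry(txt2)$references_text)[[1]]), 1L)
  no_end <- sub("//", "XX", txt, fixed = TRUE)
  expect_error(gb_parse_entry(no_end), "gi 999001")
})

test_that("header fields parse per the FTv8 layout", {
  fx <- generate_entries(2, seed = 5, profile = "minimal")
  path <- tempfile()
  write_fixture(fx, path)
  entries <- gb_read_entries(path)
  for (i in seq_along(entries)) {
    h <- entries[[i]]$header
    m <- fx$manifest[[i]]$header
    expect_equal(h$sequence_length, m$sequence_length)
    expect_equal(h$topology, m$topology)
    expect_equal(h$division_code, m$division_code)
    expect_equal(h$gi, m$gi)
    expect_equal(h$version, m$version)
    expect_equal(h$organism_name, m$organism_name)
    expect_equal(h$lineage, m$lineage)
  }
  # VERSION line with GI, and absent KEYWORDS -> empty keywords
  hdr <- paste("LOCUS       X00001                   300 bp    DNA     linear   PLN 01-JAN-2001",
               "DEFINITION  test.",
               "ACCESSION   X00001",
               "VERSION     X00001.1  GI:12345", sep = "\n")
  h <- gb_parse_header(hdr)
  expect_equal(h$version, "X00001.1")
  expect_equal(h$gi, 12345L)
  expect_equal(h$keywords, character(0))
  expect_error(gb_parse_header("DEFINITION  no locus."), "LOCUS")
})

test_that("references parse ordinals, base ranges and PUBMED ids", {
  refs <- gb_parse_references(paste(
    "REFERENCE   1  (bases 1 to 800)",
    "  AUTHORS   Doe,J.",
    "  TITLE     Something",
    "  JOURNAL   J. Test 1 (2001)",
    "   PUBMED   11223344", sep = "\n"))
  expect_length(refs, 1L)
  expect_equal(refs[[1]]$ordinal, 1L)
  expect_equal(refs[[1]]$cited_ranges$start, 1L)
  expect_equal(refs[[1]]$cited_ranges$end, 800L)
  expect_equal(refs[[1]]$pubmed_id, 11223344L)
  expect_length(gb_parse_references(""), 0L)
  # multiple ranges preserved
  refs <- gb_parse_references("REFERENCE   2  (bases 1 to 100; 300 to 400)")
  expect_equal(nrow(refs[[1]]$cited_ranges), 2L)
  expect_equal(refs[[1]]$cited_ranges$start, c(1L, 300L))
})

test_that("a reference without a base clause is widened to the whole entry", {
  fx <- generate_entries(8, seed = 21, profile = "reference_rich")
  path <- tempfile()
  write_fixture(fx, path)
  idx <- gb_index_entries(path)
  any_widened <- FALSE
  for (i in seq_len(nrow(idx))) {
    m <- fx$manifest[[i]]
    widened <- vapply(m$references, function(r) isTRUE(r$whole_entry),
                      logical(1))
    txt <- gb_read_entry_at(path, idx$header_offset[i])
    if (any(widened)) {
      any_widened <- TRUE
      expect_warning(e <- gb_parse_entry(txt), "whole-entry")
      r <- e$references[[which(widened)[1]]]
      expect_equal(r$cited_ranges,
                   data.frame(start = 1L, end = m$header$sequence_length))
    } else {
      e <- gb_parse_entry(txt)
    }
    expect_equal(vapply(e$references, `[[`, integer(1), "ordinal"),
                 vapply(m$references, `[[`, integer(1), "ordinal"))
  }
  expect_true(any_widened)  # the profile must exercise the fallback
})

test_that("feature table parsing joins wrapped values and keeps flags", {
  txt <- paste(
    "FEATURES             Location/Qualifiers",
    "     source          1..500",
    "                     /organism=\"Testus testus\"",
    "     CDS             join(10..100,201..450)",
    "                     /product=\"alpha",
    "                     beta\"",
    "                     /germline",
    "                     /translation=\"MKVL",
    "                     AAAA\"", sep = "\n")
  feats <- gb_parse_feature_table(txt)
  expect_length(feats, 2L)
  q <- feats[[2]]$qualifiers
  expect_equal(q$value[q$name == "product"], "alpha beta")
  expect_true(is.na(q$value[q$name == "germline"]))
  expect_equal(q$value[q$name == "translation"], "MKVLAAAA")
  expect_equal(vapply(feats, `[[`, integer(1), "rank"), c(0L, 1L))
  expect_error(
    gb_parse_feature_table(paste("FEATURES             Location/Qualifiers",
                                 "                     /organism=\"x\"",
                                 sep = "\n")),
    "before any feature key")
})

test_that("indexing records seekable offsets and GI numbers", {
  fx <- generate_entries(3, seed = 9, profile = "nested_gene_models")
  path <- tempfile()
  write_fixture(fx, path)
  idx <- gb_index_entries(path)
  expect_equal(nrow(idx), 3L)
  # [DERIVED] re-scan: seeking to each header offset must read LOCUS
  con <- file(path, open = "rb")
  for (off in idx$header_offset) {
    seek(con, off)
    expect_match(readLines(con, 1L), "^LOCUS")
  }
  close(con)
  # generator-recorded offsets agree
  expect_equal(idx$header_offset,
               vapply(fx$manifest, `[[`, integer(1), "header_offset"))
  expect_equal(idx$sequence_offset,
               vapply(fx$manifest, `[[`, integer(1), "sequence_offset"))
  expect_equal(idx$gi, vapply(fx$manifest, `[[`, integer(1), "gi"))
  # seeking to the sequence offset reads the first nucleotide
  con <- file(path, open = "rb")
  seek(con, idx$sequence_offset[1])
  expect_match(readChar(con, 1L), "[acgt]")
  close(con)
  # empty file -> empty index
  empty <- tempfile()
  file.create(empty)
  expect_equal(nrow(gb_index_entries(empty)), 0L)
  # '//' with no LOCUS -> indexing error naming the offset
  bad <- tempfile()
  writeLines(c("garbage", "//"), bad)
  expect_error(gb_index_entries(bad), "byte offset")
})

test_that("parse_entry round-trips the generator manifest field-for-field", {
  for (profile in c("nested_gene_models", "adversarial")) {
    fx <- generate_entries(4, seed = 13, profile = profile)
    path <- tempfile()
    write_fixture(fx, path)
    entries <- suppressWarnings(gb_read_entries(path))
    for (i in seq_along(entries)) {
      e <- entries[[i]]
      m <- fx$manifest[[i]]
      expect_identical(e$sequence, m$sequence)
      expect_equal(length(e$features), length(m$features))
      for (k in seq_along(e$features)) {
        got <- e$features[[k]]
        want <- m$features[[k]]
        expect_identical(got$key, want$key)
        gp <- got$portions
        attr(gp, "location_operator") <- NULL
        rownames(gp) <- rownames(want$portions) <- NULL
        expect_equal(gp, want$portions, info = paste(profile, i, k))
        wq <- want$qualifiers
        expect_equal(got$qualifiers$name, names(wq))
        expect_equal(got$qualifiers$value,
                     unname(vapply(wq, function(v)
                       if (is.na(v)) NA_character_ else as.character(v),
                       character(1))))
      }
    }
  }
})

test_that("sequence extraction matches the LOCUS declaration", {
  txt <- paste(
    "LOCUS       TINY                      60 bp    DNA     linear   PLN 01-JAN-2001",
    "DEFINITION  tiny.",
    "ACCESSION   TINY1",
    "VERSION     TINY1.1  GI:42",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "ORIGIN",
    paste0("        1 ", paste(rep("aaaaaaaaaa", 6), collapse = " ")),
    "//", sep = "\n")
  e <- gb_parse_entry(txt)
  expect_identical(e$sequence, strrep("a", 60))
  bad <- sub("60 bp", "61 bp", txt, fixed = TRUE)
  bad <- sub("1..60", "1..61", bad, fixed = TRUE)
  expect_error(gb_parse_entry(bad), "does not match")
})

test_that("fixture entries agree with an independent reference parser", {
  # cross-validation harness: Biopython reads the same files; feature
  # counts, keys and per-feature qualifier counts must agree
  for (profile in c("nested_gene_models", "adversarial")) {
    fx <- generate_entries(3, seed = 17, profile = profile)
    path <- tempfile(fileext = ".gb")
    write_fixture(fx, path)
    script <- tempfile(fileext = ".py")
    writeLines(c(
      "import sys, json, warnings",
      "warnings.simplefilter('ignore')",
      "from Bio import SeqIO",
      "out = []",
      "for rec in SeqIO.parse(sys.argv[1], 'genbank'):",
      "    out.append([[f.type, sum(len(v) for v in f.qualifiers.values())]",
      "                for f in rec.features])",
      "print(json.dumps(out))"), script)
    res <- system2("python", c(script, path), stdout = TRUE)
    ref <- jsonlite::fromJSON(paste(res, collapse = ""),
                              simplifyVector = FALSE)
    entries <- suppressWarnings(gb_read_entries(path))
    expect_length(ref, length(entries))
    for (i in seq_along(entries)) {
      ours <- entries[[i]]$features
      expect_equal(length(ours), length(ref[[i]]))
      expect_equal(vapply(ours, `[[`, character(1), "key"),
                   vapply(ref[[i]], function(x) x[[1]], character(1)))
      expect_equal(vapply(ours, function(f) nrow(f$qualifiers), integer(1)),
                   vapply(ref[[i]], function(x) as.integer(x[[2]]), integer(1)))
    }
  }
})
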