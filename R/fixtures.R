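#' @title Synthetic fixtures: mini ontology and GenBank flat files
#' @description Deterministic generators for (a) a ~30-term Sequence
#'   Ontology fragment in OBO format and (b) syntactically valid FTv8
#'   flat files with a ground-truth manifest (planted features,
#'   relationship trees, intron intervals, references, byte offsets).
#'   The manifest is the single source of truth for round-trip and
#'   relationship-recovery assertions, standing in for a controlled
#'   dataset with pre-established characteristics.
#' @name synthetic-fixtures
NULL

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

mini_so_spec <- function() {
  terms <- list(
    c("SO:0000001", "region"),
    c("SO:2000061", "databank_entry"),
    c("SO:0000704", "gene"),
    c("SO:0000088", "mitochondrial_gene"),
    c("SO:0000087", "nuclear_gene"),
    c("SO:0000673", "transcript"),
    c("SO:0000185", "primary_transcript"),
    c("SO:0000234", "mRNA"),
    c("SO:0000655", "ncRNA"),
    c("SO:0000253", "tRNA"),
    c("SO:0000252", "rRNA"),
    c("SO:0000274", "snRNA"),
    c("SO:0000147", "exon"),
    c("SO:0000195", "coding_exon"),
    c("SO:0000198", "noncoding_exon"),
    c("SO:0000188", "intron"),
    c("SO:0000316", "CDS"),
    c("SO:0000104", "polypeptide"),
    c("SO:0000419", "mature_protein_region"),
    c("SO:0000418", "signal_peptide"),
    c("SO:0005836", "regulatory_region"),
    c("SO:0000167", "promoter"),
    c("SO:0000141", "terminator"),
    c("SO:0000551", "polyA_signal_sequence"),
    c("SO:0000235", "TF_binding_site"),
    c("SO:0000165", "enhancer"),
    c("SO:0000140", "attenuator"),
    c("SO:0000553", "polyA_site"),
    c("SO:0000657", "repeat_region"),
    c("SO:0000203", "UTR"),
    c("SO:0000204", "five_prime_UTR"),
    c("SO:0000205", "three_prime_UTR"),
    c("SO:0000999", "obsolete_demo_term")  # is_obsolete: true
  )
  by_name <- stats::setNames(vapply(terms, `[`, character(1), 1),
                             vapply(terms, `[`, character(1), 2))
  is_a <- matrix(c(
    "gene", "region",
    "mitochondrial_gene", "gene",
    "nuclear_gene", "gene",
    "transcript", "region",
    "primary_transcript", "transcript",
    "mRNA", "transcript",
    "ncRNA", "transcript",
    "tRNA", "ncRNA",
    "rRNA", "ncRNA",
    "snRNA", "ncRNA",
    "exon", "region",
    "coding_exon", "exon",
    "noncoding_exon", "exon",
    "intron", "region",
    "CDS", "region",
    "polypeptide", "region",
    "mature_protein_region", "polypeptide",
    "signal_peptide", "polypeptide",
    "regulatory_region", "region",
    "promoter", "regulatory_region",
    "terminator", "regulatory_region",
    "polyA_signal_sequence", "regulatory_region",
    "TF_binding_site", "regulatory_region",
    "enhancer", "regulatory_region",
    "attenuator", "regulatory_region",
    "polyA_site", "region",
    "repeat_region", "region",
    "UTR", "region",
    "five_prime_UTR", "UTR",
    "three_prime_UTR", "UTR",
    "databank_entry", "region"
  ), ncol = 2, byrow = TRUE)
  rel <- matrix(c(
    "exon", "part_of", "transcript",
    "intron", "part_of", "transcript",
    "intron", "part_of", "CDS",
    "CDS", "part_of", "mRNA",
    "UTR", "part_of", "mRNA",
    "transcript", "part_of", "gene",
    "mature_protein_region", "part_of", "polypeptide",
    "regulatory_region", "member_of", "gene",
    "polypeptide", "derives_from", "CDS",
    "mature_protein_region", "derives_from", "CDS",
    "mRNA", "derives_from", "primary_transcript"
  ), ncol = 3, byrow = TRUE)
  list(terms = terms, by_name = by_name, is_a = is_a, rel = rel,
       obsolete = "SO:0000999")
}

# independent reachability oracle: plain recursive DFS over an edge list
dfs_reachable <- function(from, adj, seen = character(0)) {
  for (w in adj[[from]] %||% character(0)) {
    if (!(w %in% seen)) seen <- dfs_reachable(w, adj, c(seen, w))
  }
  seen
}

#' Generate the bundled mini Sequence Ontology fragment
#'
#' Emits a deterministic ~30-term OBO 1.2 fragment containing the exemplar
#' terms every other module is tested against: gene with a
#' mitochondrial_gene child, the transcript/mRNA/exon/intron/CDS meronomy,
#' and regulatory_region with promoter, terminator, polyA_signal_sequence
#' and TF_binding_site children.  The manifest carries term/edge counts and
#' the full expected is_a closure pair list computed by an independent
#' depth-first reachability oracle.
#'
#' @param seed unused entropy hook kept for interface symmetry; output is
#'   byte-identical for any seed.
#' @return list(obo = OBO text, manifest = list(...)).
#' @export
generate_mini_so <- function(seed = 1L) {
  sp <- mini_so_spec()
  nm <- sp$by_name
  stanza <- function(t) {
    acc <- t[1]; name <- t[2]
    lines <- c("[Term]", paste0("id: ", acc), paste0("name: ", name),
               "namespace: sequence")
    if (acc == sp$obsolete) lines <- c(lines, "is_obsolete: true")
    for (i in seq_len(nrow(sp$is_a)))
      if (nm[[sp$is_a[i, 1]]] == acc)
        lines <- c(lines, paste0("is_a: ", nm[[sp$is_a[i, 2]]], " ! ", sp$is_a[i, 2]))
    for (i in seq_len(nrow(sp$rel)))
      if (nm[[sp$rel[i, 1]]] == acc)
        lines <- c(lines, paste0("relationship: ", sp$rel[i, 2], " ",
                                 nm[[sp$rel[i, 3]]], " ! ", sp$rel[i, 3]))
    c(lines, "")
  }
  obo <- paste(c("format-version: 1.2",
                 "ontology: so-mini-synthetic", "",
                 unlist(lapply(sp$terms, stanza))), collapse = "\n")
  # expected closure by DFS reachability (oracle of record)
  live <- vapply(sp$terms, `[`, character(1), 1)
  live <- setdiff(live, sp$obsolete)
  edges <- data.frame(child = nm[sp$is_a[, 1]], parent = nm[sp$is_a[, 2]],
                      stringsAsFactors = FALSE)
  adj <- split(edges$parent, edges$child)
  pairs <- do.call(rbind, lapply(live, function(s)
    data.frame(subject = s, object = c(s, dfs_reachable(s, adj)),
               stringsAsFactors = FALSE)))
  manifest <- list(
    n_terms = length(sp$terms),
    n_live_terms = length(live),
    n_is_a = nrow(sp$is_a),
    n_rel = nrow(sp$rel),
    accession = as.list(nm),
    closure_pairs = pairs,
    regulatory_region_children = c("polyA_signal_sequence", "TF_binding_site",
                                   "terminator", "enhancer", "attenuator",
                                   "promoter"))
  list(obo = obo, manifest = manifest)
}

# ---- flat file rendering -------------------------------------------------

render_location <- function(portions, operator = NULL) {
  simple <- vapply(seq_len(nrow(portions)), function(i) {
    p <- portions[i, ]
    core <- if (p$between_bases) paste0(p$start, "^", p$end)
    else if (p$start == p$end && !p$partial5 && !p$partial3) as.character(p$start)
    else paste0(if (p$partial5) "<" else "", p$start, "..",
                if (p$partial3) ">" else "", p$end)
    if (!is.na(p$remote_accession)) core <- paste0(p$remote_accession, ":", core)
    core
  }, character(1))
  op <- operator %||% "join"
  inner <- if (length(simple) > 1L)
    paste0(op, "(", paste(simple, collapse = ","), ")") else simple
  if (all(portions$strand == "reverse") && all(is.na(portions$remote_accession)))
    paste0("complement(", inner, ")") else inner
}

portion_row <- function(start, end, strand = "forward", p5 = FALSE, p3 = FALSE,
                        between = FALSE, remote = NA_character_) {
  data.frame(start = as.integer(start), end = as.integer(end), strand = strand,
             partial5 = p5, partial3 = p3, between_bases = between,
             remote_accession = remote, stringsAsFactors = FALSE)
}

wrap_value <- function(text, width = 48L) {
  if (nchar(text) <= width) return(text)
  starts <- seq(1L, nchar(text), by = width)
  vapply(starts, function(s) substr(text, s, min(s + width - 1L, nchar(text))),
         character(1))
}

render_entry <- function(plan) {
  H <- plan$header
  lines <- c(
    sprintf("LOCUS       %-16s %10d bp    %-7s %-8s %s %s",
            H$locus_name, H$sequence_length, H$molecule_type, H$topology,
            H$division_code, H$date_gb),
    sprintf("DEFINITION  %s.", H$definition),
    sprintf("ACCESSION   %s", H$accession),
    sprintf("VERSION     %s  GI:%d", H$version, H$gi),
    sprintf("KEYWORDS    %s", if (length(H$keywords))
      paste0(paste(H$keywords, collapse = "; "), ".") else "."),
    sprintf("SOURCE      %s", H$organism_name),
    sprintf("  ORGANISM  %s", H$organism_name),
    sprintf("            %s.", paste(H$lineage, collapse = "; "))
  )
  for (r in plan$references) {
    clause <- if (isTRUE(r$whole_entry)) "" else
      sprintf("  (bases %s)", paste(sprintf("%d to %d", r$ranges$start,
                                            r$ranges$end), collapse = "; "))
    lines <- c(lines,
               sprintf("REFERENCE   %d%s", r$ordinal, clause),
               sprintf("  AUTHORS   %s", r$authors),
               sprintf("  TITLE     %s", r$title),
               sprintf("  JOURNAL   %s", r$journal))
    if (!is.na(r$pubmed)) lines <- c(lines, sprintf("   PUBMED   %d", r$pubmed))
  }
  lines <- c(lines, "FEATURES             Location/Qualifiers")
  for (f in plan$features) {
    loc <- render_location(f$portions, f$location_operator)
    if (isTRUE(f$wrap_location) && nchar(loc) > 40L) {
      pieces <- wrap_value(loc, 40L)
      lines <- c(lines, sprintf("     %-16s%s", f$key, pieces[1]),
                 paste0(strrep(" ", 21), pieces[-1]))
    } else {
      lines <- c(lines, sprintf("     %-16s%s", f$key, loc))
    }
    qn <- names(f$qualifiers)
    for (i in seq_along(f$qualifiers)) {
      v <- f$qualifiers[[i]]
      if (is.na(v)) {
        lines <- c(lines, sprintf("                     /%s", qn[i]))
      } else if (grepl("^[0-9]+$", v) ||
                 qn[i] %in% c("codon_start", "transl_table", "number",
                              "estimated_length", "citation", "direction")) {
        lines <- c(lines, sprintf("                     /%s=%s", qn[i], v))
      } else {
        pieces <- if (qn[i] == "translation") wrap_value(v)
          else if (isTRUE(f$wrap_qualifiers)) strwrap(v, width = 48L)
          else v
        first <- sprintf("                     /%s=\"%s", qn[i], pieces[1])
        if (length(pieces) == 1L) {
          lines <- c(lines, paste0(first, "\""))
        } else {
          cont <- paste0(strrep(" ", 21), pieces[-1])
          cont[length(cont)] <- paste0(cont[length(cont)], "\"")
          lines <- c(lines, first, cont)
        }
      }
    }
  }
  lines <- c(lines, "ORIGIN")
  sq <- plan$sequence
  pos <- seq(1L, nchar(sq), by = 60L)
  for (p in pos) {
    chunk <- substr(sq, p, min(p + 59L, nchar(sq)))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", p, paste(groups, collapse = " ")))
  }
  c(lines, "//")
}

random_seq <- function(n) paste(sample(c("a", "c", "g", "t"), n, replace = TRUE),
                                collapse = "")

ORGANISMS <- list(
  list(name = "Synthetica plantaris", taxon = 400001L, division = "PLN",
       lineage = c("Eukaryota", "Viridiplantae", "Synthetophyta", "Synthetica")),
  list(name = "Fabricatus insectus", taxon = 400002L, division = "INV",
       lineage = c("Eukaryota", "Metazoa", "Arthropoda", "Fabricatus")),
  list(name = "Imaginary virus 1", taxon = 400003L, division = "VRL",
       lineage = c("Viruses", "Riboviria", "Imaginaviridae")))

new_plan <- function(gi, accession, org, len, definition, keywords = character(0)) {
  list(header = list(locus_name = paste0("SYN", gi),
                     sequence_length = len, molecule_type = "DNA",
                     topology = "linear", division_code = org$division,
                     date_gb = "15-JUN-2010", definition = definition,
                     accession = accession, version = paste0(accession, ".1"),
                     gi = gi, keywords = keywords,
                     organism_name = org$name, lineage = org$lineage),
       references = list(), features = list(), sequence = random_seq(len),
       planted = list(
         relationships = data.frame(subject = integer(0), relationship = character(0),
                                    object = integer(0)),
         introns = data.frame(donor = integer(0), start = integer(0),
                              end = integer(0), strand = character(0))))
}

add_feature <- function(plan, key, portions, qualifiers = list(), ...) {
  plan$features[[length(plan$features) + 1L]] <-
    c(list(key = key, portions = portions, qualifiers = qualifiers), list(...))
  plan
}

source_feature <- function(plan, org, extra = list()) {
  quals <- c(list(organism = org$name, mol_type = "genomic DNA",
                  db_xref = paste0("taxon:", org$taxon)), extra)
  add_feature(plan, "source", portion_row(1L, plan$header$sequence_length), quals)
}

default_reference <- function(plan, ordinal = 1L) {
  plan$references[[length(plan$references) + 1L]] <- list(
    ordinal = ordinal,
    ranges = data.frame(start = 1L, end = plan$header$sequence_length),
    whole_entry = FALSE,
    authors = "Doe,J. and Roe,R.", title = "Synthetic fixture entry",
    journal = "J. Synth. Data 1, 1-2 (2010)", pubmed = NA_integer_)
  plan
}

plan_nested_gene_model <- function(plan, org, tag) {
  len <- plan$header$sequence_length
  strand <- if (stats::runif(1) < 0.3) "reverse" else "forward"
  gs <- sample(80:200, 1L)
  ge <- len - sample(50:150, 1L)
  gene_sym <- paste0("syn", tag)
  locus_tag <- paste0("SYN_", sprintf("%04d", tag))
  plan <- source_feature(plan, org)
  plan <- add_feature(plan, "gene", portion_row(gs, ge, strand),
                      list(gene = gene_sym, locus_tag = locus_tag))
  gene_i <- length(plan$features)
  has_promoter <- stats::runif(1) < 0.7
  if (has_promoter) {
    plan <- add_feature(plan, "promoter", portion_row(gs, gs + 39L, strand),
                        list(gene = gene_sym))
  }
  prom_i <- if (has_promoter) length(plan$features) else NA_integer_
  # exon structure for the mRNA
  nex <- sample(2:4, 1L)
  span0 <- gs + 60L
  span1 <- ge - 10L
  cuts <- sort(sample(seq(span0 + 50L, span1 - 50L), 2L * (nex - 1L)))
  ex_start <- c(span0, cuts[seq(2L, length(cuts), by = 2L)] + 1L)
  ex_end <- c(cuts[seq(1L, length(cuts), by = 2L)], span1)
  mrna_portions <- do.call(rbind, lapply(seq_len(nex), function(i)
    portion_row(ex_start[i], ex_end[i], strand)))
  plan <- add_feature(plan, "mRNA", mrna_portions,
                      list(gene = gene_sym, locus_tag = locus_tag,
                           product = paste0("protein ", tag)))
  mrna_i <- length(plan$features)
  cds_start <- ex_start[1] + sample(5:20, 1L)
  cds_end <- ex_end[nex] - sample(5:20, 1L)
  cds_portions <- mrna_portions
  cds_portions$start[1] <- cds_start
  cds_portions$end[nex] <- cds_end
  plan <- add_feature(plan, "CDS", cds_portions,
                      list(gene = gene_sym, locus_tag = locus_tag,
                           product = paste0("protein ", tag),
                           protein_id = sprintf("SYP%05d.1", tag),
                           codon_start = "1"))
  cds_i <- length(plan$features)
  rels <- data.frame(subject = c(mrna_i, cds_i),
                     relationship = c("part_of", "part_of"),
                     object = c(gene_i, mrna_i), stringsAsFactors = FALSE)
  if (has_promoter)
    rels <- rbind(rels, data.frame(subject = prom_i, relationship = "member_of",
                                   object = gene_i))
  gaps <- function(p) {
    if (nrow(p) < 2L) return(NULL)
    data.frame(start = p$end[-nrow(p)] + 1L, end = p$start[-1] - 1L)
  }
  introns <- rbind(
    if (!is.null(g <- gaps(mrna_portions)))
      data.frame(donor = mrna_i, start = g$start, end = g$end, strand = strand),
    if (!is.null(g <- gaps(cds_portions)))
      data.frame(donor = cds_i, start = g$start, end = g$end, strand = strand))
  plan$planted$relationships <- rels
  plan$planted$introns <- introns %||%
    data.frame(donor = integer(0), start = integer(0), end = integer(0),
               strand = character(0))
  default_reference(plan)
}

#' Generate a synthetic GenBank flat file with ground truth
#'
#' Emits `n` (or, for coverage profiles, at least enough) syntactically
#' valid FTv8 entries plus a manifest recording every planted truth: header
#' fields, byte offsets, features with portions and qualifiers, planted
#' relationship trees, planted intron intervals and references.  Output is
#' byte-identical for a fixed (n, seed, profile).
#'
#' Profiles: `minimal` (source-only entries), `nested_gene_models`
#' (gene/promoter/mRNA/CDS trees with shared gene symbols and planted
#' part_of/member_of edges and introns), `reference_rich` (multiple cited
#' base ranges, PUBMED ids, one clause-less reference), `key_coverage`
#' (every bundled feature key in at least two entries),
#' `qualifier_coverage` (every bundled qualifier exercised) and
#' `adversarial` (fuzzy/between/remote locations, order(), wrapped
#' qualifiers and locations, an unknown feature key).
#'
#' @param n number of entries (coverage profiles may emit more).
#' @param seed integer seed; also determines the GI number base.
#' @param profile one of the profiles above.
#' @return list(text = flat file text, manifest = list of per-entry ground
#'   truth).
#' @export
generate_entries <- function(n, seed = 1L, profile = "nested_gene_models") {
  profiles <- c("minimal", "nested_gene_models", "reference_rich",
                "key_coverage", "qualifier_coverage", "adversarial")
  if (!(profile %in% profiles))
    stop("unknown fixture profile: ", profile)
  if (n == 0L && !(profile %in% c("key_coverage", "qualifier_coverage")))
    return(list(text = "", manifest = list()))
  with_seed(seed, {
    gi_base <- 1000000L + (as.integer(seed) %% 10000L) * 1000L
    plans <- switch(profile,
      minimal = lapply(seq_len(n), function(k) {
        org <- ORGANISMS[[1L + (k - 1L) %% length(ORGANISMS)]]
        p <- new_plan(gi_base + k, sprintf("SYN%05d", k), org,
                      sample(100:500, 1L), "synthetic minimal entry")
        default_reference(source_feature(p, org))
      }),
      nested_gene_models = lapply(seq_len(n), function(k) {
        org <- ORGANISMS[[1L + (k - 1L) %% length(ORGANISMS)]]
        p <- new_plan(gi_base + k, sprintf("SYN%05d", k), org,
                      sample(1500:4000, 1L),
                      sprintf("synthetic nested gene model %d", k))
        plan_nested_gene_model(p, org, k)
      }),
      reference_rich = lapply(seq_len(n), function(k) {
        org <- ORGANISMS[[1L + (k - 1L) %% length(ORGANISMS)]]
        len <- sample(600:1200, 1L)
        p <- new_plan(gi_base + k, sprintf("SYN%05d", k), org, len,
                      "synthetic reference-rich entry")
        p <- source_feature(p, org)
        p <- add_feature(p, "gene", portion_row(100L, len - 100L),
                         list(gene = paste0("ref", k)))
        nref <- sample(2:4, 1L)
        for (r in seq_len(nref)) {
          no_clause <- (r == nref && stats::runif(1) < 0.4)
          a <- sample(1:(len %/% 2L), 1L)
          b <- sample((len %/% 2L + 1L):len, 1L)
          p$references[[r]] <- list(
            ordinal = r,
            ranges = if (no_clause) NULL else data.frame(start = a, end = b),
            whole_entry = no_clause,
            authors = sprintf("Author%d,A.", r),
            title = sprintf("Reference number %d", r),
            journal = sprintf("J. Synth. Data %d, %d-%d (2010)", r, a, b),
            pubmed = if (stats::runif(1) < 0.5) 20000000L + r else NA_integer_)
        }
        p
      }),
      key_coverage = {
        keys <- gb_feature_key_mapping()$feature_key
        keys_per_entry <- 5L
        slots <- rep(keys, 2L)
        n_needed <- ceiling(length(slots) / keys_per_entry)
        n_eff <- max(n, n_needed)
        assign_ix <- rep(seq_len(n_eff), length.out = length(slots))
        lapply(seq_len(n_eff), function(k) {
          org <- ORGANISMS[[1L + (k - 1L) %% length(ORGANISMS)]]
          my_keys <- setdiff(slots[assign_ix == k], "source")
          len <- 200L + 60L * (length(my_keys) + 1L)
          p <- new_plan(gi_base + k, sprintf("SYN%05d", k), org, len,
                        "synthetic key coverage entry")
          p <- source_feature(p, org)
          pos <- 10L
          for (key in my_keys) {
            p <- add_feature(p, key, portion_row(pos, pos + 49L),
                             list(note = paste0("coverage of ", key)))
            pos <- pos + 60L
          }
          default_reference(p)
        })
      },
      qualifier_coverage = {
        routing <- gb_qualifier_routing()
        flags <- c("germline", "proviral", "pseudo", "partial", "focus",
                   "macronuclear", "rearranged", "transgenic",
                   "environmental_sample", "virion", "mitochondrion",
                   "chloroplast", "chromoplast", "cyanelle", "kinetoplast")
        quals <- setdiff(routing$qualifier, c("organism", "mol_type", "db_xref"))
        per <- 12L
        n_needed <- ceiling(length(quals) / per)
        n_eff <- max(n, n_needed)
        assign_ix <- rep(seq_len(n_eff), length.out = length(quals))
        lapply(seq_len(n_eff), function(k) {
          org <- ORGANISMS[[1L + (k - 1L) %% length(ORGANISMS)]]
          my_q <- quals[assign_ix == k]
          p <- new_plan(gi_base + k, sprintf("SYN%05d", k), org,
                        sample(300:600, 1L), "synthetic qualifier coverage entry")
          mk_val <- function(q) {
            if (q %in% flags) NA_character_
            else if (q == "lat_lon") "41.90 N 12.50 E"
            else if (q == "collection_date") "12-Mar-2009"
            else if (q == "translation") paste(rep("MKV", 30L), collapse = "")
            else if (q %in% c("codon_start", "transl_table", "number",
                              "estimated_length", "citation"))
              as.character(sample(1:9, 1L))
            else paste0(q, " value ", k)
          }
          coll <- routing$qualifier[routing$route %in% c("collection", "taxonomy")]
          src_extra <- list(); feat_q <- list()
          for (q in my_q) {
            if (q %in% coll) src_extra[[q]] <- mk_val(q) else feat_q[[q]] <- mk_val(q)
          }
          p <- source_feature(p, org, src_extra)
          p <- add_feature(p, "CDS",
                           portion_row(51L, 200L),
                           c(list(gene = paste0("q", k)), feat_q))
          default_reference(p)
        })
      },
      adversarial = lapply(seq_len(n), function(k) {
        org <- ORGANISMS[[1L + (k - 1L) %% length(ORGANISMS)]]
        len <- 800L
        p <- new_plan(gi_base + k, sprintf("SYN%05d", k), org, len,
                      "synthetic adversarial entry")
        p <- source_feature(p, org)
        p <- add_feature(p, "gene", portion_row(1L, 206L, p5 = TRUE),
                         list(gene = paste0("adv", k)))
        p <- add_feature(p, "misc_feature", portion_row(123L, 124L, between = TRUE),
                         list(note = "between-base position"))
        p <- add_feature(p, "variation", portion_row(467L, 467L),
                         list(replace = "a"))
        p <- add_feature(p, "mRNA",
                         rbind(portion_row(250L, 349L, "reverse"),
                               portion_row(450L, 549L, "reverse")),
                         list(gene = paste0("adv", k),
                              note = paste(rep("a very long wrapped note value",
                                               4L), collapse = " ")),
                         wrap_qualifiers = TRUE, wrap_location = TRUE)
        p <- add_feature(p, "STS",
                         rbind(portion_row(600L, 620L),
                               portion_row(640L, 660L)),
                         list(standard_name = "ordered pair"),
                         location_operator = "order")
        p <- add_feature(p, "misc_feature",
                         rbind(portion_row(700L, 720L),
                               portion_row(100L, 202L,
                                           remote = "J00194.1")),
                         list(note = "remote accession portion"))
        p <- add_feature(p, "xyzzy", portion_row(730L, 760L),
                         list(note = "unknown feature key"))
        p$planted$introns <- data.frame(donor = 5L, start = 350L, end = 449L,
                                        strand = "reverse")
        default_reference(p)
      })
    )
    # render and compute byte offsets
    texts <- lapply(plans, render_entry)
    offset <- 0L
    manifest <- vector("list", length(plans))
    for (i in seq_along(plans)) {
      lines <- texts[[i]]
      nb <- nchar(lines, type = "bytes") + 1L
      starts <- offset + c(0L, cumsum(nb)[-length(nb)])
      i_ori <- which(startsWith(lines, "ORIGIN"))[1]
      seq_off <- if (!is.na(i_ori) && i_ori < length(lines))
        starts[i_ori + 1L] + 10L else NA_integer_
      plan <- plans[[i]]
      feats <- lapply(plan$features, function(f) {
        pf <- f$portions
        pf$rank <- seq_len(nrow(pf)) - 1L
        list(key = f$key, portions = pf,
             qualifiers = f$qualifiers,
             location_operator = f$location_operator %||% NA_character_)
      })
      n_portions <- sum(vapply(feats, function(f) nrow(f$portions), integer(1)))
      n_quals <- sum(vapply(feats, function(f) length(f$qualifiers), integer(1)))
      n_ranges <- sum(vapply(plan$references, function(r)
        if (isTRUE(r$whole_entry)) 1L else nrow(r$ranges), integer(1)))
      manifest[[i]] <- list(
        gi = plan$header$gi,
        accession = plan$header$accession,
        header = plan$header,
        header_offset = offset,
        sequence_offset = seq_off,
        sequence = plan$sequence,
        features = feats,
        references = plan$references,
        planted_relationships = plan$planted$relationships,
        planted_introns = plan$planted$introns,
        expected_fact_count = 2L + length(feats) + n_portions + n_quals +
          length(plan$references) + n_ranges)
      offset <- offset + sum(nb)
    }
    list(text = paste0(paste(unlist(texts), collapse = "\n"), "\n"),
         manifest = manifest)
  })
}

#' Write a generated fixture to disk
#'
#' @param fx result of [generate_entries()].
#' @param path output flat file path; the manifest is saved as a JSON
#'   sidecar at `<path>.manifest.json`.
#' @return invisibly, the flat file path.
#' @export
write_fixture <- function(fx, path) {
  writeLines(sub("\n$", "", fx$text), path)
  jsonlite::write_json(fx$manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
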