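# gbloadr

Ontology-driven Extract-Transform-Load for GenBank flat files, in R.

Researchers who need large slices of GenBank locally — for biodiversity
studies, barcoding, comparative annotation — face two problems: flat files
are slow to query, and much of their biology is implicit. A CDS is not
linked to the mRNA that contains it, introns are often absent as explicit
features, and references cite base ranges without naming the features they
support. `gbloadr` parses GenBank flat files (Feature Table v8 dialect),
uses Sequence Ontology (SO) knowledge and a deterministic forward-chaining
rule engine to make the implicit structure explicit, and loads everything
into a Chado-style *ontological* relational schema in an embedded SQL
database, where a single query can exploit both the `is_a` hierarchy and
the inferred feature relationships.

## What it computes

**Typing and subsumption.** Every feature is typed by an SO term (a
bundled table maps the 60 feature keys; unmapped keys fall back to
`local:` terms). The transitive closure of `is_a` is precomputed once at
setup into the `cvpath` table, so subsumption is one join: querying *gene*
also returns features typed *mitochondrial gene*.

**Admissible relationships.** From the ontology's `part_of` / `member_of`
/ `derives_from` edges the setup phase derives all admissible
(subject type, relationship, object type) triples — the graph-closure
equivalent of asking a DL reasoner for the classes subsumed by ∃R.T —
each certified by a witness path. At load time, feature f is related to g
by R iff the type pair is admissible, f and g share a `/locus_tag` or
`/gene` value (`/protein_id` for derives_from), and f's span is contained
in g's on the same strand; among competing parents the one covering the
fewest bases wins. On synthetic entries with planted gene→mRNA→CDS trees,
inferred edges equal the planted ones exactly (precision = recall = 1.0).

**Implicit introns.** Multi-portion transcript-class and CDS features
donate introns: each inter-portion gap (e₁+1, s₂−1) becomes an intron
feature on the donor's strand, `part_of` the donor, unless an explicit
intron with identical coordinates exists.

**Reference evidence.** A feature is linked to a reference iff its span is
contained in one of the reference's cited base ranges.

**Resumable loading.** Entries are indexed into jobs (seek offsets + GI)
with ready/pending/loaded states, journaled and checkpointed; each entry
loads in one transaction, with database-generated keys substituted into
later statements via symbolic `count`/`foreignCount` references. A crashed
run resumes after `reset-pending` with exactly-once effect.

**Ontological queries.** Expressions like
`regulatory_region memberOf (gene hasMember (CDS hasAnnotation product=VP35))`
compile to SQL with subsumption expansion of every term and transitive
traversal of stored part_of/member_of edges.

## Worked example

Everything below is runnable offline: the fixture generator emits valid
flat files with a ground-truth manifest, and the bundled mini-SO fragment
carries the exemplar terms.

```r
library(gbloadr)

db  <- tempfile(fileext = ".sqlite")
cfg <- gb_config(db, ledger_path = tempfile())

setup <- run_setup(cfg)        # closure + admissible triples, installed once
setup$install_counts
#> terms: 33   cvpath rows: 86

fx   <- generate_entries(5, seed = 42, profile = "nested_gene_models")
flat <- tempfile(fileext = ".gb")
write_fixture(fx, flat)

run_load(cfg, flat, setup = setup)
#>        gi status n_statements reason
#> 1 1042001 loaded           56   <NA>
#> 2 1042002 loaded           65   <NA>
#> 3 1042003 loaded           56   <NA>
#> 4 1042004 loaded           65   <NA>
#> 5 1042005 loaded           72   <NA>
```

Five entries were parsed, reasoned over and inserted (56–72 SQL statements
each: entry, sequence, features, portions, annotations, inferred
relationships and introns, reference evidence). Subsumption retrieval and
an ontological query:

```r
con <- db_connect(db)
head(db_features_by_term(con, "gene"))
#>   featureId entryAccession type spanStart spanEnd  strand
#> 1         2       SYN00001 gene        94    3789 forward
#> 2         9       SYN00002 gene       118    2539 forward
#> 3        19       SYN00003 gene       156    1847 forward
#> 4        26       SYN00004 gene       166    2800 forward
#> 5        36       SYN00005 gene       107    2729 reverse

run_query(con, 'gene hasMember (CDS hasAnnotation product="protein 2")')
#>   featureId entryAccession type spanStart spanEnd  strand
#> 1         9       SYN00002 gene       118    2539 forward
```

The second query finds the gene whose CDS carries `/product="protein 2"`,
even though the only stored edges are CDS→mRNA→gene: chain traversal is
transitive over the relationship graph. A command-line driver wrapping
the same functions (init-db, setup-ontology, fixtures, index, load,
status, reset-pending, query) ships at `inst/cli/gbloadr.R`.

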