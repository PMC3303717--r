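---
title: "Methods: ontology-driven loading of GenBank flat files"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ontology-driven loading of GenBank flat files}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbloadr)
```

## The problem

GenBank flat files state *what* is annotated on a sequence but leave much
of the biology implicit: a CDS is not linked to its mRNA, an mRNA not to
its gene, introns are frequently absent as explicit features, and
bibliographic references cite base ranges without naming the features they
support. `gbloadr` is an Extract-Transform-Load system that makes this
implicit structure explicit. It parses flat files in the Feature Table v8
dialect, uses Sequence Ontology (SO) knowledge to decide which
relationships between features are biologically admissible, infers
concrete `part_of` / `member_of` / `derives_from` edges, implicit introns
and reference evidence, and loads everything into an *ontological*
relational schema: one table for all features, typed by ontology terms,
with relationships and annotations in common tables. A precomputed
transitive closure of the `is_a` hierarchy (the `cvpath` table) lets a
single join answer subsumption queries — asking for *genes* also returns
*mitochondrial genes*.

## Ontology knowledge

`so_load_obo()` reads an OBO 1.2 stream into a term/edge graph; obsolete
terms are kept but excluded from all inference, and a cyclic `is_a`
hierarchy is rejected with a witness cycle.

Two artifacts are derived once at setup time and cached (`run_setup()`
keys the cache on an md5 fingerprint of the ontology and mapping tables):

**The is_a closure** (`so_is_a_closure()`): all pairs (subject, object)
connected by a directed `is_a` path, with the minimal path length, plus a
distance-0 self path for every live term. Self paths mean a subsumption
query returns exact-type matches without special casing; minimal distance
is stored but only pair membership matters to queries. The closure is
tested against an independent brute-force DFS reachability oracle on
hundreds of random DAGs (up to 50 nodes).

**Admissible triples** (`so_all_admissible_triples()`): a triple
(C, R, T) is admissible iff there is a directed path from C to T over
upward `is_a` edges and R edges that uses at least one R edge. This is the
graph-closure reading of asking a description-logic reasoner for the
classes subsumed by an existential restriction ∃R.T, for a class
hierarchy with transitive properties: subject-side `is_a` inheritance,
object-side upward propagation, and R-transitivity. Each triple is emitted
with a witness path that the test suite re-validates edge by edge.

### Runtime admissibility: the filler rule

Concrete feature pairs need a subtler test than raw triple lookup. The
asserted knowledge `exon part_of transcript` must license an exon
attaching to an *mRNA* (an instance of a transcript subclass), which plain
triple matching on exact types cannot do. Conversely, generalizing the
object over *all* of its ancestors is too permissive: every type
propagates up to the hierarchy root, so "mRNA derives_from *some region*"
would license `mRNA derives_from gene` — a relationship the ontology never
asserts.

`so_relationship_allowed()` therefore compares the object's concrete type
against the **fillers** of the subject's entailed restrictions: the
targets of the final R edge on any entailment path. (Tf, R, Tg) is
accepted iff some filler T′ is `is_a`-comparable with Tg — Tg a
descendant-or-self of T′, or an ancestor of it. Exon→mRNA passes (filler
`transcript` subsumes `mRNA`); mRNA→gene `derives_from` fails (filler
`primary_transcript` is incomparable with `gene`). This is the package's
admissibility semantics; the full triple set remains exposed for
inspection and auditing.

## The rule engine

Evaluation is a deterministic forward chain with stratified phases —
facts → relationships → evidence → introns → routing → statements — so no
conflict-resolution strategy is needed and the same entry with the same
ontology snapshot always yields the identical statement list. We chose
stratification over a general production system deliberately:
reproducibility and testability outweigh rule-language generality, and
the variable parts (qualifier routing, intron donor terms, the
feature-key mapping) are data files, not code.

**Facts.** Each entry becomes one header fact, one sequence fact, and
per-feature key/portion/qualifier facts plus reference and
reference-portion facts. The sequence fact carries only length and
presence: residues are never turned into working-memory facts, so the
reasoner is not loaded with megabase strings. Consequently the database
stores the sequence length, not the residues; the job index's seek
offsets allow residue retrieval from the flat file when needed.

**Relationships.** Feature f relates to g by R iff (i) the type pair is
admissible under the filler rule; (ii) f and g are qualifier-consistent:
they share a value of `/locus_tag` or `/gene` (an identical `/protein_id`
suffices for `derives_from`), or neither carries any of those qualifiers,
in which case location alone decides; (iii) f's span (the [min, max]
envelope of its local portions) is contained in g's span on the same
strand, mixed-strand features being compared strand-blind. Among multiple
qualifying parents for one R, the parent covering the fewest bases (sum
of portion lengths) wins, remaining ties going to entry order. Coverage
rather than envelope width is the right minimality notion for nested gene
models: a spliced mRNA's envelope can equal its gene's, but its exonic
coverage is strictly smaller, so a CDS lands under the mRNA rather than
the gene.

**Reference evidence.** FTv8 references cite base ranges; a feature is
linked to a reference iff its span is contained in a cited range. We chose
containment over overlap as the stricter reading of location coherence. A
reference with no parsable base clause is widened to the whole entry
(with a warning), and so supports every feature.

**Implicit introns.** For features whose type is, via the closure, a
transcript-class term or CDS (a configurable donor list), each gap
between consecutive local portions on one strand becomes an intron
feature with the donor's strand, typed with the SO intron term and
related `part_of` to its donor; an explicit intron feature with identical
coordinates suppresses the inferred one. The bundled mini-ontology
asserts `intron part_of CDS` alongside `intron part_of transcript` so
that CDS-donor introns remain admissible — a pragmatic edge in a
fragment whose job is to make the donor list work end to end.

**Qualifier routing.** The bundled routing table sends each of the 96
qualifiers to a feature annotation (typed by an SO or `local:` term), a
Collection column (sampling/voucher detail on the source organism), a
Taxonomy column (`/organism`; `/db_xref` values of the form `taxon:<id>`),
or suppression (`/translation`, by design out of scope as protein
records). Unknown qualifiers and unmapped feature keys fall back to
deterministic `local:<name>` terms stored in the same term table, so
loading is total.

**Statements.** All derived facts become one ordered list of insert and
get-or-create select statements with integer counts. A later statement
cites earlier ones through `foreign_counts`; at execution the cited
statement's database-generated key is substituted into the aligned
column. Ordering is validated (counts strictly increasing, citations only
backwards), making cycles unrepresentable. A minimal entry produces
exactly a taxonomy select, an entry insert and a sequence insert;
individual and collection-event rows appear only when collection-routed
qualifiers exist.

## The relational schema

Thirteen core tables: `ontology_term`, `cvpath`, `individual`, `entry`,
`sequence`, `sequence_feature`, `feature_portion`, `feature_annotation`,
`feature_relationship`, `reference`, `reference_evidence`, `taxonomy`,
`collection_event`, plus an auxiliary `load_log` metrics table. Features
of every kind share `sequence_feature`, typed by `ontology_term`;
coordinates are stored 1-based inclusive exactly as in the flat file
(classic Chado uses interbase coordinates — we prioritize flat-file
fidelity and document the delta here). Cited ranges live serialized in
`reference.citedRanges`; the resolved feature-reference links are rows of
`reference_evidence`. Column names are camelCase
(`individual.identificationId` is the taxonomy foreign key), table names
lowercase. The engine is embedded SQLite through DBI, with SQL kept to
the portable core; a select that creates a new `local:` term also inserts
its distance-0 cvpath self row, keeping subsumption total over terms
created at load time.

Execution is one transaction per entry: on any failure the entry's rows
vanish entirely, which is what makes crash recovery a matter of
bookkeeping rather than repair.

## Job control and exactly-once loading

Entries are indexed into jobs (file, header seek offset, sequence seek
offset, GI) with states ready → pending → loaded. The ledger persists as
a snapshot file plus an append-only journal of transitions; checkpoints
atomically rewrite the snapshot and truncate the journal. After a crash,
completed-and-journaled work is replayed from disk, jobs stuck in pending
are returned to ready by `job_reset_pending()`, and the loader skips any
GI already present in the database — together with per-entry transactions
this yields exactly-once effect under any interleaving of crash, reset
and re-run, which the tests exercise by abandoning in-memory state,
deleting the journal, and resuming. Worker parallelism is a configurable
pool honored as a dispatch contract (leases are never shared); in this
implementation execution is in-process and sequential.

## Queries

Query trees follow the pattern
`term memberOf (term hasMember (term hasAnnotation name=value))`. Every
term expands to its cvpath descendant set (distance ≥ 0);
`memberOf`/`hasMember` traverse stored `part_of`/`member_of` rows —
`derives_from` is excluded from chains — and the traversal is the
*transitive closure* of those rows, implemented as a recursive CTE. The
transitivity matters: the engine stores only minimal-span parent edges
(CDS → mRNA → gene), yet a gene must still count the CDS among its
members through the intervening mRNA. Annotation matching is exact and
case-sensitive by default with an opt-in substring mode. Results are
ordered by entry accession and feature rank, so runs are comparable.

## Synthetic fixtures

`generate_entries()` emits valid FTv8 text with a manifest recording
every planted truth (header fields, byte offsets, features, relationship
trees, intron intervals, references), and `generate_mini_so()` emits a
33-term ontology fragment whose closure ships in its own manifest,
computed by an independent DFS oracle. Profiles cover source-only
entries, nested gene models (gene/promoter/mRNA/CDS with shared gene
symbols, 2–4 exons, ~30% reverse strand), reference-rich entries
(including clause-less references), coverage of all 60 feature keys and
96 qualifiers, and adversarial syntax (fuzzy and between-base positions,
remote accession portions, `order()`, wrapped qualifiers and locations,
an unknown feature key). Sequences are uniform random `acgt` of 100–5000
bp; GI numbers are sequential from a seed-derived base. Generation is
byte-identical for a fixed (n, seed, profile).

What the generator does *not* emulate: realistic sequence composition,
taxonomic distributions, multi-gene entries, trans-spliced or circular
gene models, and qualifier typos found in historical GenBank divisions.
Passing tests therefore demonstrate correctness of parsing, inference and
loading mechanics on well-formed and adversarially formatted input — not
robustness to every irregularity in real archival data.

## Problem sizes and numerical choices

The test and acceptance suites run at desk scale by design: 200 random
DAGs of at most 50 nodes for the closure oracle, 100 nested-gene-model
entries for relationship recovery, 50-entry batches for crash-injection,
and 10-entry batches for determinism, sizes at which the brute-force
oracles are exact and the whole suite completes in about a minute.
Timings are logged per entry (`load_log`) but never asserted: they are
hardware facts, not properties of the method. There is no floating-point
numerics in the core — coordinates, counts and keys are integers — so no
tolerances are involved; equality assertions are exact.

## Known limitations

- The FTv8 key and qualifier tables are a reconstructed snapshot treated
  as configuration; swap in another revision via `gb_config()` paths.
- Remote (accession-qualified) location portions are parsed and stored
  but excluded from span computation, relationship inference and intron
  inference.
- `order()` is treated like `join()` apart from a recorded
  `location_operator` annotation; no inference distinguishes them.
- Qualifier-consistency logic (locus_tag/gene share, protein_id for
  derives_from, default-true when absent) is a reconstruction of
  under-specified behavior; it is deliberately data-independent and
  documented rather than tunable.
- The dispatcher contract is exercised in-process; a socket transport
  would have to satisfy the same ledger semantics but is not provided.
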