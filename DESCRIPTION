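Package: gbloadr
Title: Ontology-Driven Loading of GenBank Flat Files into a Relational
    Biodiversity Database
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An Extract-Transform-Load toolkit that parses GenBank flat
    files (DDBJ/EMBL/GenBank Feature Table v8 dialect), infers implicit
    relationships among sequence features (part_of, member_of,
    derives_from, implicit introns, bibliographic evidence) using the
    Sequence Ontology and a deterministic forward-chaining rule engine,
    and loads the result into a Chado-style ontological relational
    schema in an embedded SQL database.  A precomputed transitive
    closure of the is_a hierarchy (the CVPath table) supports
    subsumption-aware ontological queries of the form
    'term memberOf (term hasMember (term hasAnnotation name=value))'.
    Loading is resumable: entries are indexed into jobs with
    ready/pending/loaded states, checkpointed to disk, and loaded in
    per-entry transactions so that interrupted runs recover exactly
    once.  A synthetic fixture generator emits valid flat files with a
    ground-truth manifest so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
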