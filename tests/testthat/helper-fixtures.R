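# shared helpers: memoised ontology setup, hand-built entries, DAG oracles

`%||%` <- function(a, b) if (is.null(a)) b else a

# mini ontology + derived knowledge, computed once per test run
mini <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      graph <- so_load_obo(generate_mini_so()$obo)
      cache <<- list(graph = graph,
                     closure = so_is_a_closure(graph),
                     triples = so_all_admissible_triples(graph),
                     mapping = gb_feature_key_mapping(),
                     routing = gb_qualifier_routing(),
                     donor_terms = intron_donor_terms())
    }
    cache
  }
})

pr <- function(...) gbloadr:::portion_row(...)

# render a hand-specified entry through the fixture renderer
make_entry_text <- function(features, len = 2000L, gi = 999001L,
                            accession = "TST00001", with_reference = TRUE,
                            org = gbloadr:::ORGANISMS[[1]]) {
  plan <- gbloadr:::with_seed(42L,
    gbloadr:::new_plan(gi, accession, org, len, "hand-built test entry"))
  for (f in features)
    plan <- gbloadr:::add_feature(plan, f$key, f$portions,
                                  f$qualifiers %||% list())
  if (with_reference) plan <- gbloadr:::default_reference(plan)
  paste(gbloadr:::render_entry(plan), collapse = "\n")
}

parse_hand_entry <- function(...) {
  suppressWarnings(gb_parse_entry(make_entry_text(...)))
}

# a random DAG as an so_graph: edges always point low index -> high index
random_dag_graph <- function(n, seed, p = 2 / n) {
  set.seed(seed)
  nodes <- paste0("N", seq_len(n))
  edges <- data.frame(child = character(0), parent = character(0))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (stats::runif(1) < p)
        edges <- rbind(edges, data.frame(child = nodes[i], parent = nodes[j]))
    }
  }
  structure(list(
    terms = data.frame(accession = nodes, name = nodes, namespace = "t",
                       obsolete = FALSE),
    is_a = edges,
    rel = data.frame(subject = character(0), relationship = character(0),
                     object = character(0))),
    class = "so_graph")
}

# independent oracle: recursive DFS reachability over an edge list
oracle_reachable <- function(node, edges, from = "child", to = "parent") {
  out <- character(0)
  walk <- function(v) {
    nbrs <- edges[[to]][edges[[from]] == v]
    for (w in nbrs) {
      if (!(w %in% out)) {
        out <<- c(out, w)
        walk(w)
      }
    }
  }
  walk(node)
  out
}

# closure pair set as sorted "subject->object" strings (self pairs included)
pair_set <- function(closure) {
  sort(paste(closure$subject, closure$object, sep = "->"))
}

oracle_pair_set <- function(graph) {
  live <- graph$terms$accession[!graph$terms$obsolete]
  edges <- graph$is_a
  sort(unlist(lapply(live, function(s)
    paste(s, c(s, oracle_reachable(s, edges)), sep = "->"))))
}

fresh_db <- function() {
  path <- tempfile(fileext = ".sqlite")
  con <- db_connect(path)
  db_create_schema(con)
  list(con = con, path = path)
}

install_mini <- function(con) {
  m <- mini()
  db_install_ontology(con, m$graph, m$closure)
  m
}

edge_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(paste(df$subject, df$relationship, df$object))
}
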