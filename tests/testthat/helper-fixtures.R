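# shared test helpers: tiny table builders, an independent closure oracle,
# and python/rdflib as the conformant RDF parser and SPARQL store

tiny_table <- function(name = "t", ...) {
  cols <- list(...)
  source_table(name, as.data.frame(cols, check.names = FALSE,
                                   stringsAsFactors = FALSE))
}

triple_keys <- function(df) {
  sort(paste(df$subject, df$predicate, df$object, df$is_literal, sep = "\x01"))
}

graph_keys <- function(graph) triple_keys(graph$triples)

# Brute-force saturation oracle for the relationship-property closure:
# apply the symmetry and transitivity rules pairwise until nothing new
# appears.  Deliberately naive and independent of relation_closure().
closure_oracle <- function(triples) {
  props <- relation_properties()
  key <- function(s, p, o) paste(s, p, o, sep = "\x01")
  set <- new.env(parent = emptyenv())
  add <- function(s, p, o) {
    k <- key(s, p, o)
    if (is.null(set[[k]])) {
      set[[k]] <- c(s, p, o)
      TRUE
    } else FALSE
  }
  for (i in seq_len(nrow(triples))) {
    add(triples$subject[i], expand_iri(triples$predicate[i]), triples$object[i])
  }
  repeat {
    changed <- FALSE
    items <- as.list(set)
    for (a in items) {
      p <- a[2L]
      sem <- props[props$uri == p, ]
      if (sem$symmetric && add(a[3L], p, a[1L])) changed <- TRUE
      if (sem$transitive) {
        for (b in items) {
          if (b[2L] == p && b[1L] == a[3L] && add(a[1L], p, b[3L])) {
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  items <- as.list(set)
  if (length(items) == 0L) {
    return(data.frame(subject = character(), predicate = character(),
                      object = character(), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    subject = vapply(items, `[`, character(1), 1L),
    predicate = vapply(items, `[`, character(1), 2L),
    object = vapply(items, `[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
  df[order(df$subject, df$predicate, df$object), , drop = FALSE]
}

rel_triple_keys <- function(df) {
  sort(paste(df$subject, df$predicate, df$object, sep = "\x01"))
}

random_relation_graph <- function(max_nodes = 5L, max_edges = 6L) {
  nodes <- letters[seq_len(sample.int(max_nodes, 1L))]
  n_edges <- sample.int(max_edges, 1L)
  props <- relation_properties()$uri
  data.frame(
    subject = sample(nodes, n_edges, replace = TRUE),
    predicate = sample(props, n_edges, replace = TRUE),
    object = sample(nodes, n_edges, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

python_bin <- function() Sys.which("python")

# parse an RDF file with rdflib and return its triples as sorted keys
rdflib_triples <- function(path, format) {
  script <- paste(
    "import sys, rdflib",
    "g = rdflib.Graph()",
    "g.parse(sys.argv[1], format=sys.argv[2])",
    "for s, p, o in g:",
    "    kind = 'L' if isinstance(o, rdflib.Literal) else 'I'",
    "    print('\\x01'.join([str(s), str(p), str(o), kind]))",
    sep = "\n")
  out <- system2(python_bin(), c("-c", shQuote(script), shQuote(path), format),
                 stdout = TRUE)
  sort(out)
}

# run a SPARQL SELECT over an RDF file with rdflib; returns result rows
run_sparql <- function(rdf_path, format, query) {
  helper <- system.file("python", "sparql_select.py", package = "dwctriplify")
  qfile <- tempfile(fileext = ".rq")
  writeLines(query, qfile)
  system2(python_bin(), c(shQuote(helper), shQuote(rdf_path), format,
                          shQuote(qfile)), stdout = TRUE)
}

# the Taxon-linked-Occurrence query (Discussion-style), with the PREFIX
# declarations SPARQL requires
occurrences_with_taxa_query <- function() {
  paste(
    "PREFIX bsc: <http://biscicol.org/terms/biscicol.owl#>",
    "PREFIX dwc: <http://rs.tdwg.org/dwc/terms/>",
    "SELECT ?occurrence",
    "WHERE {",
    "?occurrence bsc:related_to ?taxon.",
    "?occurrence a dwc:Occurrence.",
    "?taxon a dwc:Taxon",
    "}",
    sep = "\n")
}

# full automated pipeline on a DwC-A path -> triple graph
auto_pipeline <- function(zip_path, vocab = load_vocabulary(), ...) {
  nd <- assign_local_ids(normalize(read_dwca(zip_path), vocab = vocab))
  cfg <- build_auto_mapping(nd, vocab, ...)
  emit(nd, cfg, vocab)
}
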