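# The four-property relationship ontology and the default class-to-class
# edge set used to auto-connect instances of the Darwin Core core classes.

#' The four relationship properties
#'
#' Returns the registry of the four relationship properties with their OWL
#' semantics: `ro:derives_from` (non-symmetric, transitive),
#' `bsc:depends_on` (non-symmetric, non-transitive), `bsc:alias_of`
#' (symmetric, transitive) and `bsc:related_to` (symmetric,
#' non-transitive).
#'
#' @return data frame with columns `uri`, `symmetric`, `transitive`.
#' @export
#' @examples
#' relation_properties()
relation_properties <- function() {
  data.frame(
    uri = c(
      "http://www.obofoundry.org/ro/ro.owl#derives_from",
      "http://biscicol.org/terms/biscicol.owl#depends_on",
      "http://biscicol.org/terms/biscicol.owl#alias_of",
      "http://biscicol.org/terms/biscicol.owl#related_to"
    ),
    symmetric  = c(FALSE, FALSE, TRUE, TRUE),
    transitive = c(TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' OWL semantics of a relationship property
#'
#' @param uri one of the four relationship property IRIs (or prefixed name,
#'   e.g. `"bsc:alias_of"`).
#' @return named logical vector `c(symmetric=, transitive=)`.
#' @export
property_semantics <- function(uri) {
  props <- relation_properties()
  i <- match(expand_iri(uri), props$uri)
  if (is.na(i)) {
    stop("unknown relationship property: ", uri,
         " (expected one of: ", paste(compress_iri(props$uri), collapse = ", "), ")")
  }
  c(symmetric = props$symmetric[i], transitive = props$transitive[i])
}

#' Load a class-relationship graph
#'
#' The class graph lists which pairs of classes are connected, and by which
#' relationship property, when both classes are present in a dataset. The
#' bundled default connects the six core classes with `bsc:depends_on` and
#' `bsc:related_to` only (`ro:derives_from` and `bsc:alias_of` are never
#' applied automatically; they remain available through explicit relation
#' mappings).
#'
#' @param path JSON file of `{subject_class, property, object_class}`
#'   records; `NULL` uses the bundled default.
#' @return object of class `class_graph`: a data frame with columns
#'   `subject_class`, `property`, `object_class`.
#' @export
load_class_graph <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "class_graph.json", package = "dwctriplify",
                        mustWork = TRUE)
  }
  edges <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  need <- c("subject_class", "property", "object_class")
  if (!is.data.frame(edges) || !all(need %in% names(edges))) {
    stop("class graph must be a JSON list of {subject_class, property, object_class}: ",
         path)
  }
  edges <- edges[need]
  edges[] <- lapply(edges, expand_iri)
  props <- relation_properties()$uri
  bad <- setdiff(edges$property, props)
  if (length(bad)) stop("class graph uses unknown relation property: ", bad[1L])
  key <- paste(edges$subject_class, edges$property, edges$object_class)
  if (anyDuplicated(key)) stop("duplicate class-graph edge: ", key[duplicated(key)][1L])
  structure(edges, class = c("class_graph", "data.frame"))
}

#' Edge connecting two classes in a class graph
#'
#' Looks up the unique edge between a pair of classes. For symmetric
#' properties the pair is matched in either order and the edge is returned
#' in its configured direction (direction is normalized to the
#' configuration; symmetry is left to OWL semantics rather than
#' materialized).
#'
#' @param class_a,class_b class IRIs.
#' @param graph a `class_graph` (default: bundled).
#' @return one-row data frame (the edge) or `NULL` if the pair is not
#'   connected.
#' @export
default_edge <- function(class_a, class_b, graph = load_class_graph()) {
  class_a <- expand_iri(class_a); class_b <- expand_iri(class_b)
  fwd <- graph$subject_class == class_a & graph$object_class == class_b
  rev <- graph$subject_class == class_b & graph$object_class == class_a
  sym <- relation_properties()$uri[relation_properties()$symmetric]
  hits <- which(fwd | (rev & graph$property %in% sym))
  if (length(hits) == 0L) return(NULL)
  if (length(hits) > 1L) {
    stop("class graph connects ", compress_iri(class_a), " and ",
         compress_iri(class_b), " with more than one edge")
  }
  as.data.frame(graph[hits, , drop = FALSE])
}

#' Symmetric/transitive closure of a relation triple set
#'
#' Computes the least superset of `triples` closed under symmetry (for the
#' symmetric properties) and transitivity (for the transitive properties).
#' This is a validation and testing utility: emitted RDF carries the OWL
#' property declarations instead of materialized inferences.
#'
#' @param triples data frame with columns `subject`, `predicate`, `object`;
#'   predicates must be registered relationship properties.
#' @return data frame of the same shape, closed, with rows in a canonical
#'   sorted order.
#' @export
relation_closure <- function(triples) {
  props <- relation_properties()
  if (is.null(triples) || nrow(triples) == 0L) {
    return(data.frame(subject = character(), predicate = character(),
                      object = character(), stringsAsFactors = FALSE))
  }
  stopifnot(all(c("subject", "predicate", "object") %in% names(triples)))
  triples$predicate <- expand_iri(triples$predicate)
  bad <- setdiff(unique(triples$predicate), props$uri)
  if (length(bad)) stop("unknown relationship property: ", bad[1L])

  out <- list()
  for (p in unique(triples$predicate)) {
    sub <- triples[triples$predicate == p, c("subject", "object"), drop = FALSE]
    sem <- property_semantics(p)
    nodes <- sort(unique(c(sub$subject, sub$object)))
    n <- length(nodes)
    adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
    adj[cbind(match(sub$subject, nodes), match(sub$object, nodes))] <- TRUE
    if (sem[["symmetric"]]) adj <- adj | t(adj)
    if (sem[["transitive"]]) {
      # Floyd-Warshall boolean closure; graphs here are small.
      for (k in seq_len(n)) adj <- adj | (adj[, k] %o% adj[k, ])
    }
    idx <- which(adj, arr.ind = TRUE)
    out[[p]] <- data.frame(subject = nodes[idx[, 1L]], predicate = p,
                           object = nodes[idx[, 2L]], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$subject, res$predicate, res$object), , drop = FALSE]
  rownames(res) <- NULL
  unique(res)
}
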