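# Triple emission: instance identifier construction, RDF triple
# generation from a mapping, and serialization to N-Triples, Turtle and
# DOT.

OWL_OBJECT_PROPERTY <- "http://www.w3.org/2002/07/owl#ObjectProperty"
OWL_SYMMETRIC <- "http://www.w3.org/2002/07/owl#SymmetricProperty"
OWL_TRANSITIVE <- "http://www.w3.org/2002/07/owl#TransitiveProperty"

# Percent-encode everything outside the RFC 3986 unreserved set, so the
# concatenated identifier is always a legal IRI path segment.  Works on
# UTF-8 bytes; uppercase hex for determinism.
percent_encode <- function(x) {
  vapply(x, function(s) {
    bytes <- as.integer(charToRaw(enc2utf8(s)))
    ok <- (bytes >= 65L & bytes <= 90L) | (bytes >= 97L & bytes <= 122L) |
      (bytes >= 48L & bytes <= 57L) | bytes %in% c(45L, 46L, 95L, 126L)
    out <- sprintf("%%%02X", bytes)
    out[ok] <- vapply(bytes[ok], function(b) rawToChar(as.raw(b)), character(1))
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Construct an instance IRI
#'
#' For entities whose identifier column is not globally unique, the
#' instance identifier is the concatenation
#' `table + "." + id_column + "_" + value`, percent-encoded and appended
#' to the base URI. Distinct (table, id column, value) triplets therefore
#' always yield distinct IRIs — uniqueness holds within one version of a
#' dataset, which is all this scheme guarantees. When the entity declares
#' globally unique identifiers, the cell value is used verbatim and must
#' itself be an absolute IRI.
#'
#' @param entity an entity mapping (list with `table`, `id_column`,
#'   `id_is_global`).
#' @param value identifier cell value(s); must be non-empty.
#' @param base_uri base IRI prefix for constructed identifiers.
#' @return character vector of absolute IRIs.
#' @export
#' @examples
#' e <- list(table = "occurrence", id_column = "occurrenceID",
#'           id_is_global = FALSE)
#' make_instance_iri(e, "MVZ:Herp:256", "http://example.org/id/")
make_instance_iri <- function(entity, value, base_uri = DEFAULT_BASE_URI) {
  if (any(!nzchar(value))) stop("empty identifier value for entity table '",
                                entity$table, "'")
  if (isTRUE(entity$id_is_global)) {
    bad <- which(!is_absolute_iri(value))
    if (length(bad)) {
      stop("entity table '", entity$table, "' declares globally unique ",
           "identifiers but value ", bad[1L], " ('", value[bad[1L]],
           "') is not an absolute IRI")
    }
    return(unname(value))
  }
  paste0(base_uri,
         percent_encode(paste0(entity$table, ".", entity$id_column, "_", value)))
}

new_triple_graph <- function(df, base_uri) {
  if (is.null(df) || nrow(df) == 0L) {
    df <- data.frame(subject = character(), predicate = character(),
                     object = character(), is_literal = logical(),
                     stringsAsFactors = FALSE)
  }
  df <- unique(df)
  df <- df[order(df$subject, df$predicate, df$object, method = "radix"), ,
           drop = FALSE]
  rownames(df) <- NULL
  structure(list(triples = df, namespaces = NS, base_uri = base_uri),
            class = "triple_graph")
}

#' @export
print.triple_graph <- function(x, ...) {
  cat("RDF graph: ", nrow(x$triples), " triple(s)\n", sep = "")
  cat("  subjects: ", length(unique(x$triples$subject)),
      ", literals: ", sum(x$triples$is_literal), "\n", sep = "")
  invisible(x)
}

# The ontology prelude: the four relationship properties declared with
# their OWL semantics, so downstream reasoners see symmetry/transitivity
# instead of materialized inferences.
ontology_prelude <- function() {
  props <- relation_properties()
  df <- data.frame(subject = props$uri, predicate = RDF_TYPE,
                   object = OWL_OBJECT_PROPERTY, is_literal = FALSE,
                   stringsAsFactors = FALSE)
  df <- rbind(df,
    data.frame(subject = props$uri[props$symmetric], predicate = RDF_TYPE,
               object = OWL_SYMMETRIC, is_literal = FALSE),
    data.frame(subject = props$uri[props$transitive], predicate = RDF_TYPE,
               object = OWL_TRANSITIVE, is_literal = FALSE))
  df
}

#' Emit RDF triples from a dataset under a mapping
#'
#' Produces, for every entity instance, one `rdf:type` triple; for every
#' attribute mapping and non-empty cell, one plain-literal triple; and for
#' every relation mapping and every linked instance pair, one relation
#' triple in the configured direction. Duplicate triples collapse (a graph
#' has set semantics). For a normalized dataset, relation pairs come from
#' the link table; for raw tables they come from shared rows or declared
#' join paths.
#'
#' @param dataset a [normalize()]d dataset, a [source_table()], or a list
#'   of source tables.
#' @param config a `mapping_config` that validates against `dataset` with
#'   zero errors.
#' @param vocab vocabulary.
#' @param prelude include the ontology prelude triples (default `TRUE`).
#' @return a `triple_graph`.
#' @export
emit <- function(dataset, config, vocab = load_vocabulary(), prelude = TRUE) {
  stopifnot(inherits(config, "mapping_config"))
  if (inherits(dataset, "normalized_dataset") && !dataset$local_ids_assigned) {
    dataset <- assign_local_ids(dataset)
  }
  val <- validate_mapping(config, dataset, vocab)
  if (!val$valid) {
    stop("mapping does not validate against the dataset:\n  ",
         paste(val$errors, collapse = "\n  "))
  }
  dt <- dataset_tables(dataset)
  base_uri <- config$base_uri
  out <- if (prelude) list(ontology_prelude()) else list()

  ents <- config$entities
  names(ents) <- vapply(ents, function(e) e$name, character(1))

  # identifier -> IRI per entity (deduplicated instance keys)
  entity_iris <- lapply(ents, function(e) {
    ids <- dt$tables[[e$table]][[e$id_column]]
    keep <- !is.na(ids) & nzchar(trimws(ids))
    ids <- unique(trimws(ids[keep]))
    if (length(ids) == 0L) return(stats::setNames(character(0), character(0)))
    stats::setNames(make_instance_iri(e, ids, base_uri), ids)
  })

  for (e in ents) {
    iris <- entity_iris[[e$name]]
    if (length(iris)) {
      out[[length(out) + 1L]] <- data.frame(
        subject = unname(iris), predicate = RDF_TYPE,
        object = expand_iri(e$class_uri), is_literal = FALSE,
        stringsAsFactors = FALSE)
    }
  }

  for (a in config$attributes) {
    e <- ents[[a$entity]]
    tab <- dt$tables[[e$table]]
    ids <- trimws(tab[[e$id_column]])
    vals <- trimws(tab[[a$column]])
    keep <- nzchar(ids) & nzchar(vals) & !is.na(ids) & !is.na(vals)
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      subject = unname(entity_iris[[a$entity]][ids[keep]]),
      predicate = expand_iri(a$property_uri),
      object = vals[keep], is_literal = TRUE, stringsAsFactors = FALSE)
  }

  for (r in config$relations) {
    pairs <- relation_pairs(dt, config, ents[[r$subject_entity]],
                            ents[[r$object_entity]])
    if (is.null(pairs) || nrow(pairs) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      subject = unname(entity_iris[[r$subject_entity]][pairs$s]),
      predicate = expand_iri(r$property_uri),
      object = unname(entity_iris[[r$object_entity]][pairs$o]),
      is_literal = FALSE, stringsAsFactors = FALSE)
  }

  new_triple_graph(do.call(rbind, out), base_uri)
}

# distinct (subject id, object id) pairs linked for a relation mapping
relation_pairs <- function(dt, config, se, oe) {
  if (!is.null(dt$normalized)) {
    nd <- dt$normalized
    scls <- expand_iri(se$class_uri); ocls <- expand_iri(oe$class_uri)
    lt <- nd$link_table
    if (!scls %in% names(lt) || !ocls %in% names(lt)) return(NULL)
    p <- data.frame(s = lt[[scls]], o = lt[[ocls]], stringsAsFactors = FALSE)
    p <- p[!is.na(p$s) & !is.na(p$o), , drop = FALSE]
    return(unique(p))
  }
  if (identical(se$table, oe$table)) {
    tab <- dt$tables[[se$table]]
    p <- data.frame(s = trimws(tab[[se$id_column]]),
                    o = trimws(tab[[oe$id_column]]), stringsAsFactors = FALSE)
    p <- p[nzchar(p$s) & nzchar(p$o), , drop = FALSE]
    return(unique(p))
  }
  path <- join_path(config, se$table, oe$table)
  if (is.null(path)) stop("no join path between tables '", se$table,
                          "' and '", oe$table, "' at emission")
  cur <- dt$tables[[se$table]]
  cur <- data.frame(s = trimws(cur[[se$id_column]]), cur,
                    check.names = FALSE, stringsAsFactors = FALSE)
  cur_table <- se$table
  for (j in path) {
    if (identical(j$left_table, cur_table)) {
      from_col <- j$left_column; to_table <- j$right_table; to_col <- j$right_column
    } else {
      from_col <- j$right_column; to_table <- j$left_table; to_col <- j$left_column
    }
    if (!from_col %in% names(cur)) {
      stop("join column '", from_col, "' missing from table '", cur_table,
           "' at emission")
    }
    nxt <- dt$tables[[to_table]]
    if (!to_col %in% names(nxt)) {
      stop("join column '", to_col, "' missing from table '", to_table,
           "' at emission")
    }
    cur <- merge(cur[, c("s", from_col), drop = FALSE], nxt,
                 by.x = from_col, by.y = to_col)
    cur_table <- to_table
  }
  p <- data.frame(s = cur$s, o = trimws(cur[[oe$id_column]]),
                  stringsAsFactors = FALSE)
  p <- p[nzchar(p$s) & nzchar(p$o), , drop = FALSE]
  unique(p)
}

# ---------------------------------------------------------------------
# serialization

escape_ntriples <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

unescape_ntriples <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[i]
    res <- ""
    while (nzchar(s)) {
      m <- regexpr("\\", s, fixed = TRUE)
      if (m < 0) { res <- paste0(res, s); break }
      res <- paste0(res, substr(s, 1L, m - 1L))
      esc <- substr(s, m + 1L, m + 1L)
      res <- paste0(res, switch(esc, n = "\n", r = "\r", t = "\t",
                                "\"" = "\"", "\\" = "\\", esc))
      s <- substring(s, m + 2L)
    }
    out[i] <- res
  }
  out
}

format_term_nt <- function(value, is_literal) {
  ifelse(is_literal,
         paste0("\"", escape_ntriples(value), "\""),
         paste0("<", value, ">"))
}

#' Serialize a graph to N-Triples
#'
#' One triple per line, lines sorted lexicographically (byte order) so the
#' same graph always serializes to the same bytes.
#'
#' @param graph a `triple_graph`.
#' @return a single character scalar (UTF-8 text, trailing newline).
#' @export
serialize_ntriples <- function(graph) {
  stopifnot(inherits(graph, "triple_graph"))
  t <- graph$triples
  if (nrow(t) == 0L) return("")
  lines <- paste0("<", t$subject, "> <", t$predicate, "> ",
                  format_term_nt(t$object, t$is_literal), " .")
  paste0(paste(sort(lines, method = "radix"), collapse = "\n"), "\n")
}

#' Parse N-Triples text
#'
#' Reads plain-literal/IRI N-Triples (the subset this package emits) back
#' into a triple table; used for round-trip checks and graph comparison.
#'
#' @param text N-Triples text.
#' @return data frame with columns `subject`, `predicate`, `object`,
#'   `is_literal`.
#' @export
parse_ntriples <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  pat <- "^<([^>]*)>\\s+<([^>]*)>\\s+(<([^>]*)>|\"((?:[^\"\\\\]|\\\\.)*)\")\\s*\\.$"
  m <- regmatches(lines, regexec(pat, lines))
  bad <- which(lengths(m) == 0L)
  if (length(bad)) stop("malformed N-Triples line: ", lines[bad[1L]])
  df <- data.frame(
    subject = vapply(m, `[`, character(1), 2L),
    predicate = vapply(m, `[`, character(1), 3L),
    object = character(length(m)),
    is_literal = vapply(m, function(g) !nzchar(g[5L]), logical(1)),
    stringsAsFactors = FALSE
  )
  iri_obj <- vapply(m, `[`, character(1), 5L)
  lit_obj <- unescape_ntriples(vapply(m, `[`, character(1), 6L))
  df$object <- ifelse(df$is_literal, lit_obj, iri_obj)
  unique(df)
}

turtle_safe_local <- function(local) {
  grepl("^[A-Za-z_][A-Za-z0-9_-]*$", local)
}

format_term_ttl <- function(value, is_literal) {
  is_literal <- rep_len(is_literal, length(value))
  out <- character(length(value))
  for (i in seq_along(value)) {
    if (is_literal[i]) {
      out[i] <- paste0("\"", escape_ntriples(value[i]), "\"")
      next
    }
    short <- compress_iri(value[i])
    if (!identical(short, value[i])) {
      local <- sub("^[a-z]+:", "", short)
      if (turtle_safe_local(local)) {
        out[i] <- short
        next
      }
    }
    out[i] <- paste0("<", value[i], ">")
  }
  out
}

#' Serialize a graph to Turtle
#'
#' Emits `@prefix` declarations for every namespace in use plus the base
#' URI, then the triples grouped by subject in sorted order. The triple
#' set is identical to the N-Triples serialization of the same graph.
#'
#' @param graph a `triple_graph`.
#' @return a single character scalar.
#' @export
serialize_turtle <- function(graph) {
  stopifnot(inherits(graph, "triple_graph"))
  t <- graph$triples
  text_for <- function(x, lit) format_term_ttl(x, lit)
  used <- character(0)
  all_iris <- c(t$subject, t$predicate, t$object[!t$is_literal])
  for (p in names(NS)) {
    if (any(startsWith(all_iris, NS[[p]]))) used <- c(used, p)
  }
  header <- if (length(used)) {
    paste0("@prefix ", used, ": <", NS[used], "> .")
  } else character(0)
  if (nrow(t) == 0L) return(paste0(paste(header, collapse = "\n"), "\n"))

  # rdf:type as 'a', predicates in prefixed form where safe
  body <- character(0)
  for (s in sort(unique(t$subject), method = "radix")) {
    rows <- t[t$subject == s, , drop = FALSE]
    rows <- rows[order(rows$predicate != RDF_TYPE, rows$predicate, rows$object,
                       method = "radix"), , drop = FALSE]
    pred <- ifelse(rows$predicate == RDF_TYPE, "a",
                   text_for(rows$predicate, FALSE))
    obj <- text_for(rows$object, rows$is_literal)
    po <- paste0("    ", pred, " ", obj)
    body <- c(body,
              paste0(text_for(s, FALSE), "\n",
                     paste(po, collapse = " ;\n"), " ."))
  }
  paste0(paste(header, collapse = "\n"), "\n\n",
         paste(body, collapse = "\n\n"), "\n")
}

#' Serialize a graph to DOT
#'
#' Renders the graph in the Graphviz DOT language: one node per distinct
#' subject or object (IRIs shown in prefixed short form, literals as boxed
#' labels), one edge per triple labeled with the prefixed predicate.
#'
#' @param graph a `triple_graph`.
#' @return a single character scalar (a `digraph`).
#' @export
serialize_dot <- function(graph) {
  stopifnot(inherits(graph, "triple_graph"))
  t <- graph$triples
  if (nrow(t) == 0L) return("digraph {\n}\n")
  esc <- function(x) gsub("\"", "\\\"", gsub("\\", "\\\\", x, fixed = TRUE),
                          fixed = TRUE)
  subj_key <- paste0("I", t$subject)
  obj_key <- ifelse(t$is_literal, paste0("L", t$object), paste0("I", t$object))
  nodes <- sort(unique(c(subj_key, obj_key)), method = "radix")
  node_id <- stats::setNames(paste0("n", seq_along(nodes)), nodes)
  defs <- vapply(nodes, function(k) {
    if (startsWith(k, "L")) {
      paste0("  ", node_id[[k]], " [label=\"", esc(substring(k, 2L)),
             "\", shape=box];")
    } else {
      paste0("  ", node_id[[k]], " [label=\"",
             esc(compress_iri(substring(k, 2L))), "\", shape=ellipse];")
    }
  }, character(1))
  edges <- paste0("  ", node_id[subj_key], " -> ", node_id[obj_key],
                  " [label=\"", esc(compress_iri(t$predicate)), "\"];")
  paste0("digraph {\n", paste(defs, collapse = "\n"), "\n",
         paste(sort(edges, method = "radix"), collapse = "\n"), "\n}\n")
}

#' Serialize a graph
#'
#' @param graph a `triple_graph`.
#' @param format one of `"ntriples"`, `"turtle"`, `"dot"`.
#' @return serialized text.
#' @export
serialize_graph <- function(graph, format = c("ntriples", "turtle", "dot")) {
  format <- match.arg(format)
  switch(format,
         ntriples = serialize_ntriples(graph),
         turtle = serialize_turtle(graph),
         dot = serialize_dot(graph))
}
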