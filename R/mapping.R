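# The four configuration steps — joins, entities, attributes, relations —
# modeled as a mapping configuration that can be built automatically for
# Darwin Core Archives, saved as a reusable JSON file, edited by hand, and
# validated against a dataset before emission.

MAPPING_SCHEMA_VERSION <- 1L

DEFAULT_BASE_URI <- "http://example.org/id/"

new_mapping_config <- function(base_uri, fingerprint, joins, entities,
                               attributes, relations) {
  structure(list(
    version = MAPPING_SCHEMA_VERSION,
    base_uri = base_uri,
    fingerprint = fingerprint,
    joins = joins,
    entities = entities,
    attributes = attributes,
    relations = relations
  ), class = "mapping_config")
}

#' @export
print.mapping_config <- function(x, ...) {
  cat("Mapping configuration (schema version ", x$version, ")\n", sep = "")
  cat("  base URI:  ", x$base_uri, "\n", sep = "")
  cat("  joins:     ", length(x$joins), "\n", sep = "")
  cat("  entities:  ", length(x$entities), " (",
      paste(vapply(x$entities, function(e) compress_iri(e$class_uri), character(1)),
            collapse = ", "), ")\n", sep = "")
  cat("  attributes:", length(x$attributes), "\n", sep = "")
  cat("  relations: ", length(x$relations), "\n", sep = "")
  invisible(x)
}

# uniform view of a dataset for validation/emission: named list of data
# frames plus, for normalized datasets, the link table keyed by class
dataset_tables <- function(dataset) {
  if (inherits(dataset, "normalized_dataset")) {
    tabs <- dataset$instance_tables
    names(tabs) <- dataset$table_name[names(dataset$instance_tables)]
    # expose the identifier column under its mapped name as well as 'id'
    for (cls in names(dataset$instance_tables)) {
      nm <- dataset$table_name[[cls]]
      idc <- dataset$id_column[[cls]]
      if (!idc %in% names(tabs[[nm]])) tabs[[nm]][[idc]] <- tabs[[nm]]$id
    }
    list(tables = tabs, normalized = dataset)
  } else if (inherits(dataset, "source_table")) {
    list(tables = stats::setNames(list(dataset$data), dataset$name),
         normalized = NULL)
  } else {
    stopifnot(is.list(dataset),
              all(vapply(dataset, inherits, logical(1), "source_table")))
    list(tables = stats::setNames(lapply(dataset, `[[`, "data"),
                                  vapply(dataset, `[[`, character(1), "name")),
         normalized = NULL)
  }
}

#' Build a mapping automatically from a normalized dataset
#'
#' Completes all four configuration steps with no user intervention: one
#' entity per detected class (using the explicit ID column, or the
#' synthesized `localID` column, never treated as globally unique), one
#' attribute per assigned literal column, and one relation per
#' class-graph edge whose two classes are both present (routed through the
#' normalization link table). The result is deterministic for a given
#' dataset, vocabulary and class graph.
#'
#' @param normalized a [normalize()]d dataset.
#' @param vocab vocabulary.
#' @param graph a [load_class_graph()] class graph.
#' @param base_uri base IRI prefix for constructed instance identifiers.
#' @return a `mapping_config`.
#' @export
build_auto_mapping <- function(normalized, vocab = load_vocabulary(),
                               graph = load_class_graph(),
                               base_uri = DEFAULT_BASE_URI) {
  stopifnot(inherits(normalized, "normalized_dataset"))
  classes <- names(normalized$instance_tables)
  if (length(classes) == 0L) {
    stop("no vocabulary classes present; automatic mapping is impossible — ",
         "supply a mapping file to configure the conversion manually")
  }
  entities <- lapply(classes, function(cls) {
    list(name = unname(normalized$table_name[[cls]]),
         table = unname(normalized$table_name[[cls]]),
         id_column = unname(normalized$id_column[[cls]]),
         class_uri = cls,
         id_is_global = FALSE)
  })
  attributes <- list()
  for (cls in classes) {
    terms <- normalized$literal_terms[[cls]]
    for (col in names(terms)) {
      if (is.na(terms[[col]])) next
      attributes[[length(attributes) + 1L]] <- list(
        entity = unname(normalized$table_name[[cls]]),
        column = col,
        property_uri = unname(terms[[col]]))
    }
  }
  relations <- list()
  for (i in seq_len(nrow(graph))) {
    s <- graph$subject_class[i]; o <- graph$object_class[i]
    if (s %in% classes && o %in% classes) {
      relations[[length(relations) + 1L]] <- list(
        subject_entity = unname(normalized$table_name[[s]]),
        property_uri = graph$property[i],
        object_entity = unname(normalized$table_name[[o]]))
    }
  }
  # degenerate case: Location/GeologicalContext columns without Event
  # columns connect directly to the hub class with related_to
  event_cls <- expand_iri("dwc:Event")
  hub <- normalized$hub_class
  if (!event_cls %in% classes && hub %in% classes) {
    for (cls in intersect(c(expand_iri("dcterms:Location"),
                            expand_iri("dwc:GeologicalContext")), classes)) {
      touched <- any(vapply(relations, function(r)
        normalized$table_name[[cls]] %in% c(r$subject_entity, r$object_entity),
        logical(1)))
      if (!touched && cls != hub) {
        relations[[length(relations) + 1L]] <- list(
          subject_entity = unname(normalized$table_name[[hub]]),
          property_uri = expand_iri("bsc:related_to"),
          object_entity = unname(normalized$table_name[[cls]]))
      }
    }
  }
  dt <- dataset_tables(normalized)
  fingerprint <- lapply(dt$tables, names)
  new_mapping_config(base_uri, fingerprint, joins = list(),
                     entities = entities, attributes = attributes,
                     relations = relations)
}

resolve_entity <- function(config, name) {
  hits <- which(vapply(config$entities, function(e) identical(e$name, name),
                       logical(1)))
  if (length(hits) == 1L) config$entities[[hits]] else NULL
}

#' Validate a mapping against a dataset
#'
#' Checks that every reference in the mapping resolves (tables, columns,
#' entities), that attribute properties are literal properties and relation
#' properties are among the four relationship properties, and that relation
#' endpoints are connectable (shared link table, shared table, or a join
#' path). Domain mismatches — a property mapped onto an entity of a class
#' other than its domain — are warnings, not errors.
#'
#' @param config a `mapping_config`.
#' @param dataset a [normalize()]d dataset, a [source_table()], or a list
#'   of source tables.
#' @param vocab vocabulary.
#' @return list with `errors`, `warnings` and `valid` (`TRUE` iff no
#'   errors).
#' @export
validate_mapping <- function(config, dataset, vocab = load_vocabulary()) {
  stopifnot(inherits(config, "mapping_config"))
  errors <- character(0); warnings <- character(0)
  dt <- dataset_tables(dataset)
  tabs <- dt$tables

  if (!nzchar(config$base_uri %||% "")) errors <- c(errors, "base_uri is empty")

  ent_names <- vapply(config$entities, function(e) e$name %||% e$table, character(1))
  if (anyDuplicated(ent_names)) {
    errors <- c(errors, paste0("duplicate entity name: ",
                               ent_names[duplicated(ent_names)][1L]))
  }
  ent_key <- vapply(config$entities, function(e)
    paste(e$table, e$id_column, e$class_uri), character(1))
  if (anyDuplicated(ent_key)) {
    errors <- c(errors, "duplicate entity (table, id_column, class) triplet")
  }

  for (e in config$entities) {
    if (!e$table %in% names(tabs)) {
      errors <- c(errors, paste0("entity '", e$name, "': table '", e$table,
                                 "' not found in dataset"))
      next
    }
    if (!e$id_column %in% names(tabs[[e$table]])) {
      errors <- c(errors, paste0("entity '", e$name, "': id column '",
                                 e$id_column, "' not found in table '",
                                 e$table, "'"))
    }
    cls <- tryCatch(term_for_column(vocab, e$class_uri), error = function(err) NULL)
    if (is.null(cls) || cls$kind != "CLASS") {
      errors <- c(errors, paste0("entity '", e$name, "': class ", e$class_uri,
                                 " is not a registered class"))
    }
  }

  for (a in config$attributes) {
    e <- resolve_entity(config, a$entity)
    if (is.null(e)) {
      errors <- c(errors, paste0("attribute on unknown entity '", a$entity, "'"))
      next
    }
    if (e$table %in% names(tabs) && !a$column %in% names(tabs[[e$table]])) {
      errors <- c(errors, paste0("attribute column '", a$column,
                                 "' not found in table '", e$table, "'"))
    }
    term <- tryCatch(term_for_column(vocab, a$property_uri),
                     error = function(err) NULL)
    if (is.null(term) || term$kind != "LITERAL_PROPERTY") {
      errors <- c(errors, paste0("attribute property ", a$property_uri,
                                 " is not a literal property in the vocabulary"))
    } else if (!is.na(term$domain) && !identical(term$domain, e$class_uri)) {
      warnings <- c(warnings, paste0("attribute ", compress_iri(term$uri),
                                     " has domain ", compress_iri(term$domain),
                                     " but is mapped onto an entity of class ",
                                     compress_iri(e$class_uri)))
    } else if (is.na(term$domain)) {
      warnings <- c(warnings, paste0("attribute ", compress_iri(term$uri),
                                     " is a record-level term without a ",
                                     "single-class domain"))
    }
  }

  rel_props <- relation_properties()$uri
  for (r in config$relations) {
    if (!expand_iri(r$property_uri) %in% rel_props) {
      errors <- c(errors, paste0("relation property ", r$property_uri,
                                 " is not one of the four relationship properties"))
    }
    se <- resolve_entity(config, r$subject_entity)
    oe <- resolve_entity(config, r$object_entity)
    if (is.null(se) || is.null(oe)) {
      errors <- c(errors, paste0("relation references unknown entity '",
                                 if (is.null(se)) r$subject_entity else r$object_entity,
                                 "'"))
      next
    }
    if (is.null(dt$normalized)) {
      path <- join_path(config, se$table, oe$table)
      if (is.null(path)) {
        errors <- c(errors, paste0("relation ", se$name, " -> ", oe$name,
                                   ": no join path between tables '", se$table,
                                   "' and '", oe$table, "'"))
      }
    }
  }

  for (j in config$joins) {
    for (side in list(c(j$left_table, j$left_column),
                      c(j$right_table, j$right_column))) {
      if (!side[1L] %in% names(tabs)) {
        errors <- c(errors, paste0("join references unknown table '", side[1L], "'"))
      } else if (!side[2L] %in% names(tabs[[side[1L]]])) {
        errors <- c(errors, paste0("join column '", side[2L],
                                   "' not found in table '", side[1L], "'"))
      }
    }
  }

  list(errors = errors, warnings = warnings, valid = length(errors) == 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# BFS over the join graph; returns a list of joins forming a path between
# two tables (empty list when the tables are identical), or NULL.
join_path <- function(config, from, to) {
  if (identical(from, to)) return(list())
  edges <- config$joins
  if (length(edges) == 0L) return(NULL)
  frontier <- list(list(table = from, path = list()))
  seen <- from
  while (length(frontier)) {
    nxt <- list()
    for (node in frontier) {
      for (j in edges) {
        other <- NULL
        if (identical(j$left_table, node$table)) other <- j$right_table
        if (identical(j$right_table, node$table)) other <- j$left_table
        if (is.null(other) || other %in% seen) next
        path <- c(node$path, list(j))
        if (identical(other, to)) return(path)
        seen <- c(seen, other)
        nxt[[length(nxt) + 1L]] <- list(table = other, path = path)
      }
    }
    frontier <- nxt
  }
  NULL
}

canonical_config <- function(x) {
  x$fingerprint <- lapply(x$fingerprint, function(v) as.character(unlist(v)))
  joins <- lapply(x$joins, function(j) list(
    left_table = j$left_table, left_column = j$left_column,
    right_table = j$right_table, right_column = j$right_column))
  entities <- lapply(x$entities, function(e) list(
    name = e$name %||% e$table, table = e$table, id_column = e$id_column,
    class_uri = expand_iri(e$class_uri),
    id_is_global = isTRUE(e$id_is_global)))
  attributes <- lapply(x$attributes, function(a) list(
    entity = a$entity, column = a$column,
    property_uri = expand_iri(a$property_uri)))
  relations <- lapply(x$relations, function(r) list(
    subject_entity = r$subject_entity,
    property_uri = expand_iri(r$property_uri),
    object_entity = r$object_entity))
  new_mapping_config(x$base_uri, x$fingerprint, joins, entities,
                     attributes, relations)
}

#' Save a mapping file
#'
#' Writes the mapping as versioned JSON. Saving, loading and saving again
#' is byte-stable.
#'
#' @param config a `mapping_config`.
#' @param path output path.
#' @export
save_mapping <- function(config, path) {
  stopifnot(inherits(config, "mapping_config"))
  config <- canonical_config(config)
  json <- jsonlite::toJSON(unclass(config), pretty = TRUE, auto_unbox = TRUE,
                           null = "null", digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Load a mapping file
#'
#' Parses and schema-checks a JSON mapping file. Structural violations
#' (missing keys, an unknown relation property) are parse errors naming
#' the offending element; a fingerprint that does not match the dataset it
#' is later applied to only triggers a warning at validation time.
#'
#' @param path mapping file path.
#' @return a `mapping_config`.
#' @export
load_mapping <- function(path) {
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) stop("mapping file is not valid JSON: ",
                                         path, " (", conditionMessage(e), ")"))
  for (key in c("version", "base_uri", "entities")) {
    if (is.null(x[[key]])) stop("mapping file missing required key $.", key)
  }
  if (as.integer(x$version) > MAPPING_SCHEMA_VERSION) {
    stop("mapping file schema version ", x$version, " is newer than supported (",
         MAPPING_SCHEMA_VERSION, ")")
  }
  check_fields <- function(items, fields, where) {
    for (i in seq_along(items)) {
      missing <- setdiff(fields, names(items[[i]]))
      if (length(missing)) {
        stop("mapping file: $.", where, "[", i - 1L, "] missing field '",
             missing[1L], "'")
      }
    }
  }
  check_fields(x$entities, c("table", "id_column", "class_uri"), "entities")
  check_fields(x$attributes, c("entity", "column", "property_uri"), "attributes")
  check_fields(x$relations, c("subject_entity", "property_uri", "object_entity"),
               "relations")
  check_fields(x$joins, c("left_table", "left_column", "right_table",
                          "right_column"), "joins")
  rel_props <- relation_properties()$uri
  for (i in seq_along(x$relations)) {
    p <- expand_iri(x$relations[[i]]$property_uri)
    if (!p %in% rel_props) {
      stop("mapping file: $.relations[", i - 1L, "].property_uri '",
           x$relations[[i]]$property_uri,
           "' is not one of the four relationship properties")
    }
  }
  canonical_config(new_mapping_config(
    x$base_uri, x$fingerprint %||% list(),
    x$joins %||% list(), x$entities %||% list(),
    x$attributes %||% list(), x$relations %||% list()
  ))
}

#' Warn when a mapping's fingerprint does not match a dataset
#'
#' @param config a `mapping_config`.
#' @param dataset the dataset the mapping is about to drive.
#' @return `TRUE` (invisibly) if the structure matches.
#' @export
check_fingerprint <- function(config, dataset) {
  dt <- dataset_tables(dataset)
  want <- config$fingerprint
  if (length(want) == 0L) return(invisible(TRUE))
  have <- lapply(dt$tables, names)
  bad <- names(want)[vapply(names(want), function(nm) {
    !nm %in% names(have) || !all(unlist(want[[nm]]) %in% have[[nm]])
  }, logical(1))]
  if (length(bad)) {
    warning("mapping fingerprint mismatch: table(s) ",
            paste0("'", bad, "'", collapse = ", "),
            " differ from the dataset the mapping was built for")
  }
  invisible(length(bad) == 0L)
}
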