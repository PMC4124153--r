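# Normalization: analyze column terms to find which classes are present,
# split columns into per-class instance tables, deduplicate, and
# synthesize local integer identifiers where class IDs are missing.

KEY_SEP <- "\x1f"  # unit separator; cannot occur in trimmed cell text

# short per-class table name used in constructed identifiers
class_table_name <- function(class_uri) {
  tolower(split_iri(class_uri)[["local"]])
}

#' Detect which classes a table's columns describe
#'
#' Each column is resolved against the vocabulary — through its declared
#' term URI when the table came from a Darwin Core Archive, otherwise by
#' its header name — and assigned to the term's domain class. ID-term
#' columns additionally flag their class as explicitly identified. Unknown
#' columns and record-level terms without a single-class domain stay
#' unassigned (that is not an error; they are listed in the report).
#'
#' @param table a [source_table()].
#' @param vocab a [load_vocabulary()] vocabulary.
#' @return object of class `class_assignment`: list with `column_term`,
#'   `column_class`, `column_kind` (per column, `NA` = unassigned),
#'   `id_columns` (named, class IRI -> header), `classes` (present class
#'   IRIs) and `unassigned` (headers).
#' @export
detect_classes <- function(table, vocab) {
  stopifnot(inherits(table, "source_table"), inherits(vocab, "dwc_vocabulary"))
  headers <- names(table$data)
  n <- length(headers)
  column_term <- column_class <- column_kind <- rep(NA_character_, n)
  for (j in seq_len(n)) {
    declared <- table$terms[j]
    term <- NULL
    if (!is.na(declared) && nzchar(declared)) {
      term <- tryCatch(term_for_column(vocab, declared), error = function(e) NULL)
    }
    if (is.null(term)) {
      term <- tryCatch(term_for_column(vocab, headers[j]), error = function(e) NULL)
    }
    if (is.null(term) || term$kind == "CLASS") next
    cls <- class_of_term(vocab, term$uri)
    if (is.null(cls)) next  # domainless record-level term
    column_term[j] <- term$uri
    column_class[j] <- cls
    column_kind[j] <- term$kind
  }
  id_columns <- character(0)
  for (j in which(column_kind == "ID_TERM")) {
    id_columns[column_class[j]] <- headers[j]
  }
  classes <- unique(column_class[!is.na(column_class)])
  # keep the conventional core-class order, then any others
  classes <- c(intersect(vocab$core_classes, classes),
               setdiff(classes, vocab$core_classes))
  structure(list(
    column_term = column_term, column_class = column_class,
    column_kind = column_kind, id_columns = id_columns,
    classes = classes, unassigned = headers[is.na(column_class)]
  ), class = "class_assignment")
}

# normalize one table under an assignment; returns pieces for one dataset
normalize_one <- function(table, assignment, strict = FALSE) {
  data <- table$data
  data[] <- lapply(data, function(col) {
    col <- trimws(col)
    col[is.na(col)] <- ""
    col
  })
  headers <- names(data)
  nr <- nrow(data)
  instance_tables <- list(); literal_terms <- list(); id_column <- character(0)
  explicit_id <- logical(0); provenance <- list(); duplicates <- integer(0)
  conflicts <- 0L
  link <- list()

  for (cls in assignment$classes) {
    cols <- which(assignment$column_class == cls)
    idj <- cols[assignment$column_kind[cols] == "ID_TERM"]
    litj <- setdiff(cols, idj)
    has_id <- length(idj) == 1L
    proj <- data[, cols, drop = FALSE]
    filled <- if (nr) rowSums(proj != "") > 0 else logical(0)

    if (has_id) {
      key <- data[[idj]]
      skip <- filled & !nzchar(key)
      if (any(skip)) {
        msg <- paste0("class ", compress_iri(cls), ": ", sum(skip),
                      " row(s) with literal values but empty ",
                      headers[idj], "; instances skipped")
        if (strict) stop(msg) else warning(msg)
        filled <- filled & nzchar(key)
      }
    } else {
      key <- do.call(paste, c(data[, litj, drop = FALSE], sep = KEY_SEP))
      if (length(litj) == 0L) key <- rep("", nr)
    }
    key[!filled] <- NA_character_

    keep <- which(filled & !duplicated(key))
    if (has_id) {
      # explicit-ID conflict: same identifier, differing literal tuple
      tup <- do.call(paste, c(data[, litj, drop = FALSE], sep = KEY_SEP))
      if (length(litj) == 0L) tup <- rep("", nr)
      seen <- stats::setNames(tup[keep], key[keep])
      dupes <- which(filled & duplicated(key))
      bad <- dupes[seen[key[dupes]] != tup[dupes]]
      if (length(bad)) {
        conflicts <- conflicts + length(bad)
        msg <- paste0("class ", compress_iri(cls), ": ", length(bad),
                      " identifier value(s) reused with differing literals; ",
                      "first-seen values kept")
        if (strict) stop(msg) else warning(msg)
      }
    }

    inst <- data.frame(id = key[keep], stringsAsFactors = FALSE)
    for (j in litj) inst[[headers[j]]] <- data[keep, j]
    rownames(inst) <- NULL
    instance_tables[[cls]] <- inst
    literal_terms[[cls]] <- stats::setNames(assignment$column_term[litj], headers[litj])
    id_column[cls] <- if (has_id) headers[idj] else "localID"
    explicit_id[cls] <- has_id
    duplicates[cls] <- sum(filled) - length(keep)
    provenance[[cls]] <- split(which(filled), key[which(filled)])
    link[[cls]] <- key
  }

  link_table <- as.data.frame(link, check.names = FALSE, optional = TRUE,
                              stringsAsFactors = FALSE)
  if (length(link) && nr) names(link_table) <- names(link)
  list(instance_tables = instance_tables, literal_terms = literal_terms,
       id_column = id_column, explicit_id = explicit_id,
       provenance = provenance, link_table = link_table,
       duplicates = duplicates, conflicts = conflicts)
}

#' Normalize a table into per-class instance tables
#'
#' Projects each row onto the columns of every class present, drops
#' projections that are entirely empty, collapses duplicate instances
#' (keyed by the explicit identifier where the class has an ID column,
#' otherwise by the full tuple of literal values), and records, per source
#' row, which instance of each class it contributed to (the link table,
#' which preserves row co-occurrence for relation emission).
#'
#' @param table a [source_table()] (or a `dwc_archive`, whose core and
#'   extension tables are normalized and linked through the core id).
#' @param assignment a [detect_classes()] result for `table`; computed
#'   automatically for archives.
#' @param vocab vocabulary (needed for archives).
#' @param strict upgrade data-quality warnings (identifier conflicts,
#'   empty identifiers) to errors.
#' @return object of class `normalized_dataset`: `instance_tables` (class
#'   IRI -> data frame, first column `id`), `link_table` (one column per
#'   class, one row per source row), `id_column`, `explicit_id`,
#'   `table_name`, `literal_terms`, `hub_class` and a `report`.
#' @export
normalize <- function(table, assignment = NULL, vocab = load_vocabulary(),
                      strict = FALSE) {
  if (inherits(table, "dwc_archive")) {
    return(normalize_archive(table, vocab, strict = strict))
  }
  stopifnot(inherits(table, "source_table"))
  if (is.null(assignment)) assignment <- detect_classes(table, vocab)
  if (length(assignment$classes) == 0L) {
    stop("no vocabulary classes detected in table '", table$name,
         "'; supply a mapping file to configure the conversion manually")
  }
  parts <- normalize_one(table, assignment, strict = strict)
  hub <- assignment$classes[1L]
  build_normalized(parts, hub, assignment)
}

build_normalized <- function(parts, hub_class, assignment) {
  classes <- names(parts$instance_tables)
  structure(list(
    instance_tables = parts$instance_tables,
    link_table = parts$link_table,
    literal_terms = parts$literal_terms,
    id_column = parts$id_column,
    explicit_id = parts$explicit_id,
    table_name = stats::setNames(vapply(classes, class_table_name, character(1)),
                                 classes),
    provenance = parts$provenance,
    hub_class = hub_class,
    local_ids_assigned = FALSE,
    report = list(
      classes = classes,
      unassigned_columns = assignment$unassigned,
      duplicates_removed = parts$duplicates,
      id_conflicts = parts$conflicts
    )
  ), class = "normalized_dataset")
}

normalize_archive <- function(archive, vocab, strict = FALSE) {
  core_assign <- detect_classes(archive$core, vocab)
  if (length(core_assign$classes) == 0L) {
    stop("no vocabulary classes detected in DwC-A core '", archive$core$name,
         "'; supply a mapping file to configure the conversion manually")
  }
  core <- normalize_one(archive$core, core_assign, strict = strict)

  # hub class: the core row type when registered, else first detected class
  hub <- tryCatch(class_of_term(vocab, archive$core_row_type),
                  error = function(e) NULL)
  if (is.null(hub) || !hub %in% core_assign$classes) hub <- core_assign$classes[1L]

  parts <- core
  unassigned <- core_assign$unassigned
  core_ids <- archive$core$data[[archive$core_id_index]]

  for (ext in archive$extensions) {
    assign_e <- detect_classes(ext$table, vocab)
    # the coreid column joins, it does not describe a class of its own
    assign_e$column_class[ext$coreid_index] <- NA_character_
    assign_e$column_kind[ext$coreid_index] <- NA_character_
    assign_e$column_term[ext$coreid_index] <- NA_character_
    still <- unique(stats::na.omit(assign_e$column_class))
    assign_e$classes <- intersect(assign_e$classes, still)
    assign_e$id_columns <- assign_e$id_columns[
      names(assign_e$id_columns) %in% assign_e$classes]
    if (length(assign_e$classes) == 0L) next
    pe <- normalize_one(ext$table, assign_e, strict = strict)
    unassigned <- union(unassigned, assign_e$unassigned)

    # map extension rows to the hub instance of their core row
    coreid <- trimws(ext$table$data[[ext$coreid_index]])
    core_row <- match(coreid, trimws(core_ids))
    hub_key <- rep(NA_character_, length(coreid))
    if (hub %in% names(core$link_table)) {
      hub_key[!is.na(core_row)] <- core$link_table[[hub]][core_row[!is.na(core_row)]]
    }

    for (cls in names(pe$instance_tables)) {
      if (cls %in% names(parts$instance_tables)) {
        merged <- rbind(parts$instance_tables[[cls]], pe$instance_tables[[cls]])
        dup <- duplicated(merged$id)
        parts$duplicates[cls] <- parts$duplicates[cls] + sum(dup)
        parts$instance_tables[[cls]] <- merged[!dup, , drop = FALSE]
      } else {
        parts$instance_tables[[cls]] <- pe$instance_tables[[cls]]
        parts$literal_terms[[cls]] <- pe$literal_terms[[cls]]
        parts$id_column[cls] <- pe$id_column[[cls]]
        parts$explicit_id[cls] <- pe$explicit_id[[cls]]
        parts$duplicates[cls] <- pe$duplicates[[cls]]
        parts$provenance[[cls]] <- pe$provenance[[cls]]
      }
    }

    # extension link rows: extension-class instances + the hub instance
    ext_link <- pe$link_table
    ext_link[[hub]] <- hub_key
    for (cls in setdiff(names(parts$link_table), names(ext_link))) {
      ext_link[[cls]] <- NA_character_
    }
    for (cls in setdiff(names(ext_link), names(parts$link_table))) {
      parts$link_table[[cls]] <- NA_character_
    }
    parts$link_table <- rbind(parts$link_table[names(ext_link)], ext_link)
    parts$conflicts <- parts$conflicts + pe$conflicts
  }

  core_assign$unassigned <- unassigned
  build_normalized(parts, hub, core_assign)
}

#' Assign local integer identifiers
#'
#' For every class that lacks an explicit ID column, instances are numbered
#' `1..n` in first-appearance order of their deduplicated value tuple
#' (deterministic in the input row order). Classes with explicit
#' identifiers are untouched. The synthesized identifier column is named
#' `localID`.
#'
#' @param dataset a [normalize()]d dataset.
#' @return the dataset with local identifiers in place.
#' @export
assign_local_ids <- function(dataset) {
  stopifnot(inherits(dataset, "normalized_dataset"))
  for (cls in names(dataset$instance_tables)) {
    if (isTRUE(dataset$explicit_id[[cls]])) next
    inst <- dataset$instance_tables[[cls]]
    if (nrow(inst) == 0L) next
    new_id <- as.character(seq_len(nrow(inst)))
    remap <- stats::setNames(new_id, inst$id)
    if (cls %in% names(dataset$link_table)) {
      old <- dataset$link_table[[cls]]
      dataset$link_table[[cls]] <- ifelse(is.na(old), NA_character_, remap[old])
    }
    names(dataset$provenance[[cls]]) <-
      remap[names(dataset$provenance[[cls]])]
    inst$id <- new_id
    dataset$instance_tables[[cls]] <- inst
  }
  dataset$local_ids_assigned <- TRUE
  dataset
}

#' @export
print.normalized_dataset <- function(x, ...) {
  cat("Normalized dataset (hub class: ", compress_iri(x$hub_class), ")\n", sep = "")
  for (cls in names(x$instance_tables)) {
    cat("  ", compress_iri(cls), ": ", nrow(x$instance_tables[[cls]]),
        " instance(s), id column '", x$id_column[[cls]], "'",
        if (!x$explicit_id[[cls]]) " (synthesized)", "\n", sep = "")
  }
  cat("  link table: ", nrow(x$link_table), " row(s)\n", sep = "")
  if (length(x$report$unassigned_columns)) {
    cat("  unassigned columns:",
        paste(x$report$unassigned_columns, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Normalization report
#'
#' @param dataset a [normalize()]d dataset.
#' @return list: classes detected, unassigned columns, duplicates removed
#'   per class, identifier conflicts.
#' @export
normalization_report <- function(dataset) {
  stopifnot(inherits(dataset, "normalized_dataset"))
  dataset$report
}
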