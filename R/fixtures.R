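# Synthetic Darwin Core Archives and CSVs with controlled structure:
# which classes are present, which have explicit ID columns, how much
# duplication and missingness — plus a ground-truth manifest computed by
# construction, so every pipeline stage can be checked without downloads.

FIXTURE_CLASS_COLUMNS <- list(
  Occurrence = c("recordedBy", "catalogNumber"),
  Taxon = c("scientificName", "family"),
  Event = c("eventDate", "habitat"),
  Location = c("locality", "country"),
  GeologicalContext = c("formation", "group"),
  Identification = c("identifiedBy", "dateIdentified")
)

FIXTURE_POOLS <- list(
  recordedBy = c("B. Field", "R. Collector", "M. Surveyor"),
  catalogNumber = c("10231", "10458", "20017", "20553"),
  scientificName = c("Quercus alba", "Picea abies", "Turdus merula",
                     "Apis mellifera", "Canis lupus"),
  family = c("Fagaceae", "Pinaceae", "Turdidae", "Apidae", "Canidae"),
  eventDate = c("2012-05-14", "2013-06-02", "2013-07-19", "2014-01-30"),
  habitat = c("montane forest", "wet meadow", "urban park"),
  locality = c("Boulder Creek", "Gainesville Ridge", "Berkeley Marsh",
               "Mono Lake Shore"),
  country = c("United States", "Canada", "Mexico"),
  formation = c("Morrison", "Green River", "Niobrara"),
  group = c("San Rafael", "Mesaverde"),
  identifiedBy = c("J. Smith", "A. Garcia", "L. Chen"),
  dateIdentified = c("2014-02-11", "2014-03-05", "2014-04-22")
)

FIXTURE_ID_COLUMN <- c(
  Occurrence = "occurrenceID", Taxon = "taxonID", Event = "eventID",
  Location = "locationID", GeologicalContext = "geologicalContextID",
  Identification = "identificationID"
)

#' Specify a synthetic occurrence-core fixture
#'
#' Defines the structure of a generated dataset: number of rows, which of
#' the six core classes have columns, which of those carry an explicit ID
#' column, the per-class fraction of filled rows that duplicate an earlier
#' instance, and the per-class fraction of rows whose cells for that class
#' are empty (the Occurrence core itself is always filled). Values come
#' from small fixed pools so duplication is controllable; the first
#' literal column of each class carries the instance number, which makes
#' distinct instances distinct by construction.
#'
#' @param n_rows number of data rows.
#' @param classes class short names, a subset of the six core classes;
#'   must include `"Occurrence"`.
#' @param explicit_id_classes classes that get an explicit ID column.
#' @param duplicate_fraction scalar or named per-class fraction in [0, 1].
#' @param missing_cell_fraction scalar or named per-class fraction in
#'   [0, 1] (ignored for Occurrence).
#' @param seed integer seed; the same spec always yields byte-identical
#'   archives.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_rows = 25L,
                         classes = c("Occurrence", "Taxon"),
                         explicit_id_classes = "Occurrence",
                         duplicate_fraction = 0,
                         missing_cell_fraction = 0,
                         seed = 1L) {
  stopifnot(n_rows >= 0, "Occurrence" %in% classes,
            all(classes %in% names(FIXTURE_CLASS_COLUMNS)),
            all(explicit_id_classes %in% classes))
  frac <- function(x, what) {
    if (is.null(names(x))) x <- stats::setNames(rep(x[1L], length(classes)), classes)
    x <- x[classes]; x[is.na(x)] <- 0
    names(x) <- classes
    stopifnot(all(x >= 0 & x <= 1))
    x
  }
  structure(list(
    n_rows = as.integer(n_rows),
    classes = classes,
    explicit_id_classes = explicit_id_classes,
    duplicate_fraction = frac(duplicate_fraction),
    missing_cell_fraction = frac(missing_cell_fraction),
    seed = as.integer(seed)
  ), class = "fixture_spec")
}

# Build the core table and ground truth for a spec.  Deterministic: all
# randomness is drawn from a private RNG stream seeded by spec$seed.
build_fixture <- function(spec, base_uri = DEFAULT_BASE_URI) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  n <- spec$n_rows
  headers <- character(0)
  columns <- list()
  tuple_idx <- list()    # per class: instance index per row (NA = empty)
  m_of <- integer(0)     # per class: number of distinct instances

  for (cls in spec$classes) {
    miss <- if (cls == "Occurrence") 0 else spec$missing_cell_fraction[[cls]]
    n_filled <- if (n == 0L) 0L else round(n * (1 - miss))
    filled <- if (n_filled > 0L) sort(sample.int(n, n_filled)) else integer(0)
    dup <- spec$duplicate_fraction[[cls]]
    m <- if (n_filled == 0L) 0L else max(1L, round(n_filled * (1 - dup)))
    m <- min(m, n_filled)
    idx <- rep(NA_integer_, n)
    if (n_filled > 0L) {
      assign_idx <- c(seq_len(m),
                      if (n_filled > m) sample.int(m, n_filled - m, replace = TRUE))
      idx[filled] <- assign_idx
    }
    tuple_idx[[cls]] <- idx
    m_of[cls] <- m

    explicit <- cls %in% spec$explicit_id_classes
    lit_cols <- FIXTURE_CLASS_COLUMNS[[cls]]
    if (explicit) {
      idcol <- FIXTURE_ID_COLUMN[[cls]]
      prefix <- toupper(substr(cls, 1L, 3L))
      vals <- ifelse(is.na(idx), "", sprintf("%s%04d", prefix, idx))
      headers <- c(headers, idcol); columns[[idcol]] <- vals
    }
    for (k in seq_along(lit_cols)) {
      col <- lit_cols[k]
      pool <- FIXTURE_POOLS[[col]]
      val_of <- function(i) {
        base <- pool[((i - 1L) %% length(pool)) + 1L]
        if (k == 1L) paste0(base, " ", i) else base
      }
      vals <- ifelse(is.na(idx), "", vapply(ifelse(is.na(idx), 1L, idx),
                                            val_of, character(1)))
      headers <- c(headers, col); columns[[col]] <- vals
    }
  }

  df <- as.data.frame(columns, check.names = FALSE, stringsAsFactors = FALSE)
  if (n == 0L) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(headers)),
                                        headers), check.names = FALSE)
  }

  # ground truth
  instance_counts <- as.list(m_of)
  class_uri <- function(short) {
    if (short == "Location") "http://purl.org/dc/terms/Location"
    else paste0("http://rs.tdwg.org/dwc/terms/", short)
  }
  graph <- load_class_graph()
  link_counts <- list()
  for (i in seq_len(nrow(graph))) {
    s_short <- names(which(vapply(spec$classes, class_uri, character(1)) ==
                             graph$subject_class[i]))
    o_short <- names(which(vapply(spec$classes, class_uri, character(1)) ==
                             graph$object_class[i]))
    if (length(s_short) == 0L || length(o_short) == 0L) next
    si <- tuple_idx[[s_short]]; oi <- tuple_idx[[o_short]]
    both <- !is.na(si) & !is.na(oi)
    link_counts[[paste0(tolower(s_short), "|", tolower(o_short))]] <-
      nrow(unique(data.frame(s = si[both], o = oi[both])))
  }
  if (!"Event" %in% spec$classes) {
    for (cls in intersect(c("Location", "GeologicalContext"), spec$classes)) {
      si <- tuple_idx[["Occurrence"]]; oi <- tuple_idx[[cls]]
      both <- !is.na(si) & !is.na(oi)
      link_counts[[paste0("occurrence|", tolower(cls))]] <-
        nrow(unique(data.frame(s = si[both], o = oi[both])))
    }
  }

  # literal cells on deduplicated instances, per class
  literal_cells <- list()
  for (cls in spec$classes) {
    literal_cells[[tolower(cls)]] <-
      m_of[[cls]] * length(FIXTURE_CLASS_COLUMNS[[cls]])
  }

  occ_idx <- tuple_idx[["Occurrence"]]
  with_taxa <- if ("Taxon" %in% spec$classes) {
    rows <- which(!is.na(occ_idx) & !is.na(tuple_idx[["Taxon"]]))
    if (length(rows) == 0L) character(0) else {
      ids <- sprintf("OCC%04d", sort(unique(occ_idx[rows])))
      # constructed-identifier formula; fixture ids are plain alphanumerics,
      # so percent-encoding is the identity here
      paste0(base_uri, "occurrence.occurrenceID_", ids)
    }
  } else character(0)

  manifest <- list(
    instance_counts = stats::setNames(instance_counts, tolower(names(instance_counts))),
    link_counts = link_counts,
    literal_cell_counts = literal_cells,
    expected_occurrences_with_taxa = with_taxa
  )
  list(table = df, manifest = manifest)
}

fixture_term_uri <- function(header) {
  if (header %in% c("type")) return(paste0(NS[["dcterms"]], header))
  paste0(NS[["dwc"]], header)
}

#' Generate a synthetic Darwin Core Archive
#'
#' Writes a conformant occurrence-core DwC-A (meta.xml plus a
#' comma-delimited core file whose columns are genuine Darwin Core terms
#' for the requested classes) and a JSON ground-truth manifest holding the
#' expected per-class instance counts, link counts, literal cell counts,
#' and the occurrence IRIs that should carry a Taxon link.
#'
#' @param spec a [fixture_spec()].
#' @param path output `.zip` path; the manifest is written to
#'   `<path>.manifest.json`.
#' @param base_uri base IRI used for the manifest's expected IRIs.
#' @return invisibly, `list(path, manifest_path, manifest)`.
#' @export
generate_dwca <- function(spec, path, base_uri = DEFAULT_BASE_URI) {
  stopifnot(inherits(spec, "fixture_spec"))
  fx <- build_fixture(spec, base_uri)
  df <- fx$table

  header_line <- paste(names(df), collapse = ",")
  data_lines <- if (nrow(df)) do.call(paste, c(df, sep = ",")) else character(0)
  core_text <- paste0(paste(c(header_line, data_lines), collapse = "\n"), "\n")

  id_index <- which(names(df) == "occurrenceID") - 1L
  if (length(id_index) == 0L) id_index <- 0L
  fields <- paste0(
    "    <field index=\"", seq_along(names(df)) - 1L, "\" term=\"",
    vapply(names(df), fixture_term_uri, character(1)), "\"/>",
    collapse = "\n")
  meta <- paste0(
    "<archive xmlns=\"http://rs.tdwg.org/dwc/text/\">\n",
    "  <core encoding=\"UTF-8\" fieldsTerminatedBy=\",\" linesTerminatedBy=\"\\n\"",
    " fieldsEnclosedBy=\"\" ignoreHeaderLines=\"1\"",
    " rowType=\"http://rs.tdwg.org/dwc/terms/Occurrence\">\n",
    "    <files><location>occurrence.txt</location></files>\n",
    "    <id index=\"", id_index, "\"/>\n",
    fields, "\n",
    "  </core>\n",
    "</archive>\n")

  write_stored_zip(list(
    "meta.xml" = charToRaw(meta),
    "occurrence.txt" = charToRaw(core_text)
  ), path)

  manifest_path <- paste0(path, ".manifest.json")
  writeLines(jsonlite::toJSON(fx$manifest, pretty = TRUE, auto_unbox = TRUE,
                              digits = NA),
             manifest_path, useBytes = TRUE)
  invisible(list(path = path, manifest_path = manifest_path,
                 manifest = fx$manifest))
}

#' Generate a synthetic CSV file
#'
#' The same core table as [generate_dwca()], written as a plain RFC 4180
#' CSV (no meta.xml, so class detection must rely on the header names).
#'
#' @inheritParams generate_dwca
#' @param path output `.csv` path.
#' @export
generate_csv <- function(spec, path, base_uri = DEFAULT_BASE_URI) {
  stopifnot(inherits(spec, "fixture_spec"))
  fx <- build_fixture(spec, base_uri)
  utils::write.csv(fx$table, path, row.names = FALSE, quote = FALSE)
  manifest_path <- paste0(path, ".manifest.json")
  writeLines(jsonlite::toJSON(fx$manifest, pretty = TRUE, auto_unbox = TRUE,
                              digits = NA),
             manifest_path, useBytes = TRUE)
  invisible(list(path = path, manifest_path = manifest_path,
                 manifest = fx$manifest))
}
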