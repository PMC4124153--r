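# Working RDF vocabulary: Darwin Core classes, per-class ID terms, and
# literal properties with domain classes, loaded from a bundled term
# snapshot (a tab-separated table: uri, kind, domain, label).

TERM_KINDS <- c("CLASS", "ID_TERM", "LITERAL_PROPERTY", "RELATION_PROPERTY")

# The six Darwin Core core classes, in their conventional order.
DWC_CORE_CLASSES <- c(
  "http://rs.tdwg.org/dwc/terms/Occurrence",
  "http://rs.tdwg.org/dwc/terms/Event",
  "http://purl.org/dc/terms/Location",
  "http://rs.tdwg.org/dwc/terms/GeologicalContext",
  "http://rs.tdwg.org/dwc/terms/Identification",
  "http://rs.tdwg.org/dwc/terms/Taxon"
)

DC_CLASSES <- paste0("http://purl.org/dc/terms/", c(
  "Location", "Agent", "Image", "MovingImage", "PhysicalObject", "Sound", "Text"
))

#' Load the working Darwin Core vocabulary
#'
#' Reads a term snapshot — a tab-separated table with columns `uri`, `kind`,
#' `domain` and `label` — into an indexed vocabulary object. The bundled
#' default snapshot pins the Darwin Core term list from before the addition
#' of `dwc:MaterialSample`: six core classes (Occurrence, Event, Location,
#' GeologicalContext, Identification, Taxon), one ID term per core class,
#' seven Dublin Core classes, and the literal properties with their domain
#' classes taken from each term's `organizedInClass` assignment. Seven
#' record-level terms (`dcterms:type`, `dwc:institutionID`,
#' `dwc:collectionID`, `dwc:institutionCode`, `dwc:collectionCode`,
#' `dwc:ownerInstitutionCode`, `dwc:basisOfRecord`) carry the domain
#' `dwc:Occurrence`; the remaining record-level terms are kept without a
#' single-class domain.
#'
#' @param snapshot path to a snapshot table; `NULL` uses the bundled default.
#' @return an object of class `dwc_vocabulary`: a list with elements
#'   `terms` (data frame of uri, local_name, prefix, kind, domain, label),
#'   `core_classes` and `id_term_of` (named character, class IRI -> ID term
#'   IRI).
#' @export
#' @examples
#' v <- load_vocabulary()
#' length(v$core_classes)
load_vocabulary <- function(snapshot = NULL) {
  if (is.null(snapshot)) {
    snapshot <- system.file("extdata", "dwc_terms.tsv", package = "dwctriplify",
                            mustWork = TRUE)
  }
  raw <- utils::read.delim(snapshot, colClasses = "character", quote = "",
                           check.names = FALSE, na.strings = NULL)
  need <- c("uri", "kind", "domain")
  if (!all(need %in% names(raw))) {
    stop("vocabulary snapshot must have columns uri, kind, domain: ", snapshot)
  }
  if (!"label" %in% names(raw)) raw$label <- ""
  bad <- which(!raw$kind %in% TERM_KINDS | !nzchar(raw$uri))
  if (length(bad)) {
    stop("malformed snapshot row ", bad[1L] + 1L, ": uri='", raw$uri[bad[1L]],
         "' kind='", raw$kind[bad[1L]], "'")
  }
  if (anyDuplicated(raw$uri)) {
    stop("duplicate term URI in snapshot: ",
         paste(unique(raw$uri[duplicated(raw$uri)]), collapse = ", "))
  }

  parts <- t(vapply(raw$uri, split_iri, character(2)))
  prefix <- vapply(parts[, 1L], function(ns) {
    hit <- names(NS)[match(ns, NS)]
    if (is.na(hit)) "" else hit
  }, character(1), USE.NAMES = FALSE)
  terms <- data.frame(
    uri = raw$uri, local_name = parts[, 2L], prefix = prefix,
    kind = raw$kind, domain = ifelse(nzchar(raw$domain), raw$domain, NA_character_),
    label = raw$label, stringsAsFactors = FALSE, row.names = NULL
  )

  classes <- terms$uri[terms$kind == "CLASS"]
  dangling <- terms$domain[!is.na(terms$domain) & !terms$domain %in% classes]
  if (length(dangling)) {
    stop("snapshot domain references unregistered class: ", dangling[1L])
  }
  if (!all(DWC_CORE_CLASSES %in% classes)) {
    stop("snapshot is missing core classes: ",
         paste(setdiff(DWC_CORE_CLASSES, classes), collapse = ", "))
  }

  idt <- terms[terms$kind == "ID_TERM", , drop = FALSE]
  if (anyNA(idt$domain)) stop("ID term without a class domain: ",
                              idt$uri[is.na(idt$domain)][1L])
  if (anyDuplicated(idt$domain)) {
    stop("class with more than one ID term: ",
         idt$domain[duplicated(idt$domain)][1L])
  }
  missing_id <- setdiff(DWC_CORE_CLASSES, idt$domain)
  if (length(missing_id)) stop("core class without ID term: ", missing_id[1L])
  id_term_of <- stats::setNames(idt$uri, idt$domain)

  structure(
    list(terms = terms, core_classes = DWC_CORE_CLASSES, id_term_of = id_term_of),
    class = "dwc_vocabulary"
  )
}

#' @export
print.dwc_vocabulary <- function(x, ...) {
  cat("Darwin Core working vocabulary\n")
  cat("  terms:            ", nrow(x$terms), "\n")
  cat("  core classes:     ", length(x$core_classes), "\n")
  cat("  classes (total):  ", sum(x$terms$kind == "CLASS"), "\n")
  cat("  ID terms:         ", sum(x$terms$kind == "ID_TERM"), "\n")
  cat("  literal properties:", sum(x$terms$kind == "LITERAL_PROPERTY"), "\n")
  invisible(x)
}

#' Resolve a column header or URI to a vocabulary term
#'
#' Full IRIs and prefixed names (`dwc:scientificName`) are matched exactly
#' after prefix expansion; bare names (`scientificName`) are matched
#' case-insensitively against registered local names. Unknown names resolve
#' to `NULL`; a bare name matching two terms in different namespaces is an
#' error listing the candidates.
#'
#' @param vocab a `dwc_vocabulary`.
#' @param column a single column header, term URI, or prefixed name.
#' @return a one-row data frame (the term) or `NULL`.
#' @export
term_for_column <- function(vocab, column) {
  stopifnot(inherits(vocab, "dwc_vocabulary"), is.character(column),
            length(column) == 1L)
  terms <- vocab$terms
  uri <- expand_iri(trimws(column))
  if (grepl("^[A-Za-z][A-Za-z0-9+.-]*://", uri)) {
    i <- match(uri, terms$uri)
    return(if (is.na(i)) NULL else terms[i, , drop = FALSE])
  }
  hits <- which(tolower(terms$local_name) == tolower(uri))
  if (length(hits) == 0L) return(NULL)
  if (length(hits) > 1L) {
    stop("ambiguous column name '", column, "' matches: ",
         paste(terms$uri[hits], collapse = ", "))
  }
  terms[hits, , drop = FALSE]
}

#' Domain class of a registered term
#'
#' For a literal property or ID term, returns its domain class; for a class
#' term, the class itself; for a record-level term without a single-class
#' domain, `NULL`.
#'
#' @param vocab a `dwc_vocabulary`.
#' @param term_uri a registered term URI (or prefixed name).
#' @return a class IRI or `NULL`.
#' @export
class_of_term <- function(vocab, term_uri) {
  stopifnot(inherits(vocab, "dwc_vocabulary"))
  uri <- expand_iri(term_uri)
  i <- match(uri, vocab$terms$uri)
  if (is.na(i)) stop("term not registered in vocabulary: ", term_uri)
  row <- vocab$terms[i, ]
  if (row$kind == "CLASS") return(row$uri)
  if (is.na(row$domain)) NULL else row$domain
}
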