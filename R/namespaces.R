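#' @keywords internal
"_PACKAGE"

# Short-form URI prefixes used throughout the package.  These are the
# namespaces of the working vocabulary (Darwin Core + Dublin Core), the
# relationship ontology (bsc, ro) and the W3C core vocabularies.
NS <- c(
  bsc           = "http://biscicol.org/terms/biscicol.owl#",
  dcterms       = "http://purl.org/dc/terms/",
  dwc           = "http://rs.tdwg.org/dwc/terms/",
  dwcattributes = "http://rs.tdwg.org/dwc/terms/attributes/",
  owl           = "http://www.w3.org/2002/07/owl#",
  rdf           = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  ro            = "http://www.obofoundry.org/ro/ro.owl#"
)

RDF_TYPE <- paste0(NS[["rdf"]], "type")

#' Expand a prefixed name to a full IRI
#'
#' Expands names of the form `"dwc:scientificName"` against the package's
#' namespace table. Strings that are already absolute IRIs are returned
#' unchanged.
#'
#' @param x character vector of prefixed names or IRIs.
#' @return character vector of absolute IRIs.
#' @export
#' @examples
#' expand_iri("dwc:Occurrence")
expand_iri <- function(x) {
  vapply(x, function(s) {
    if (grepl("^[A-Za-z][A-Za-z0-9+.-]*://", s)) return(s)
    m <- regmatches(s, regexec("^([A-Za-z][A-Za-z0-9]*):(.*)$", s))[[1]]
    if (length(m) == 3L && m[2] %in% names(NS)) paste0(NS[[m[2]]], m[3]) else s
  }, character(1), USE.NAMES = FALSE)
}

# Compress an IRI to prefix:local form where a namespace matches; otherwise
# return the IRI unchanged.
compress_iri <- function(x) {
  vapply(x, function(s) {
    for (p in names(NS)) {
      ns <- NS[[p]]
      if (startsWith(s, ns)) {
        local <- substring(s, nchar(ns) + 1L)
        if (nzchar(local) && !grepl("[/#:]", local)) return(paste0(p, ":", local))
      }
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

# Split an IRI into (namespace, local name) at the last '#' or '/'.
split_iri <- function(uri) {
  pos <- regexpr("[#/][^#/]*$", uri)
  if (pos < 0) return(c(ns = "", local = uri))
  c(ns = substr(uri, 1L, pos), local = substring(uri, pos + 1L))
}

is_absolute_iri <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9+.-]*:\\S+$", x) &
    !grepl("[<>\"{}|^`\\\\[:space:][:cntrl:]]", x)
}
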