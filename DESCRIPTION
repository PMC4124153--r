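Package: dwctriplify
Title: Convert Tabular Biodiversity Data to RDF Using Darwin Core
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts tabular biodiversity data (Darwin Core Archives, CSV
    files, and spreadsheet workbooks) into RDF. Columns are matched against a
    bundled Darwin Core term snapshot to detect which classes (Occurrence,
    Event, Location, GeologicalContext, Identification, Taxon) are present,
    the data are normalized into per-class instance tables with duplicates
    removed, instance identifiers are constructed deterministically, and
    triples are emitted under a small relationship ontology of four
    properties (derives_from, depends_on, alias_of, related_to) with OWL
    symmetric/transitive semantics. Output serializations are N-Triples,
    Turtle, and Graphviz DOT. Mappings between columns and RDF entities,
    attributes, and relations can be built automatically for Darwin Core
    Archives, saved as reusable JSON mapping files, and edited by hand for
    batch conversion from the command line.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    xml2,
    utils,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    readxl,
    optparse
Config/testthat/edition: 3
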