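# dwctriplify

Convert tabular biodiversity data — Darwin Core Archives, CSV files,
spreadsheet workbooks — into RDF.

## Why

Species-occurrence data are overwhelmingly published as flat tables in
which every row mixes several implicit entities: the occurrence record
itself, the collecting event, the locality, the taxon, the
identification. Almost none of those entities carry identifiers, which
makes the data hard to link across institutions and awkward to query at
the level of *things and their relationships* rather than rows and
columns.

`dwctriplify` closes that gap for desk-scale datasets:

1. **Detect** — column headers (or the term URIs a DwC-A's `meta.xml`
   declares) are resolved against a bundled Darwin Core vocabulary
   snapshot in which every property carries a domain class; the classes
   present in the table fall out of that analysis.
2. **Normalize** — columns are split into per-class instance tables,
   duplicates are eliminated (keyed on the explicit identifier where one
   exists, on the full value tuple where none does), and a link table
   preserves which instances co-occurred on each source row.
3. **Identify** — classes without identifiers get local integers in
   first-appearance order, and every instance receives a deterministic
   IRI built as `base_uri` + percent-encoded
   `table + "." + id_column + "_" + value`. Columns declared globally
   unique pass through verbatim.
4. **Emit** — one `rdf:type` triple per instance, one plain-literal
   triple per non-empty mapped cell, and relation triples drawn from a
   small four-property ontology (`ro:derives_from`, `bsc:depends_on`,
   `bsc:alias_of`, `bsc:related_to`, with OWL symmetric/transitive
   declarations included as a prelude). Default class-to-class edges use
   only `depends_on` and `related_to`, e.g. Occurrence `related_to`
   Taxon and Occurrence `depends_on` Event.
5. **Serialize** — sorted, reproducible N-Triples or Turtle, or Graphviz
   DOT for visualization.

The four configuration steps (joins, entities, attributes, relations) are
completed automatically for DwC-As, and can be exported as a reusable
JSON mapping file, edited by hand, and replayed for batch conversion.

## Worked example

Generate a small synthetic archive (25 occurrence rows, taxon columns
filled on 10 of them, event columns on all) and convert it:

```r
library(dwctriplify)

spec <- fixture_spec(n_rows = 25, classes = c("Occurrence", "Taxon", "Event"),
                     missing_cell_fraction = c(Taxon = 0.6), seed = 7)
generate_dwca(spec, "example.zip")

res <- triplify_run("example.zip", out = "example.nt",
                    write_mapping = "example-mapping.json")
#> [example.zip] classes: dwc:Occurrence, dwc:Event, dwc:Taxon; duplicates removed: 0
#> [example.zip] 223 triples -> example.nt
```

The graph holds 223 triples: 8 ontology-prelude triples, 60 `rdf:type`
triples (25 occurrences + 25 events + 10 taxa, one per deduplicated
instance), 120 literal triples (one per non-empty cell on a deduplicated
instance), and 35 relation triples (10 Occurrence `related_to` Taxon
pairs — only the rows whose taxon cells are filled — plus 25 Occurrence
`depends_on` Event pairs). The output starts:

```
<http://biscicol.org/terms/biscicol.owl#alias_of> <http://www.w3.org/1999/02/22-rdf-syntax-ns#type> <http://www.w3.org/2002/07/owl#ObjectProperty> .
<http://biscicol.org/terms/biscicol.owl#alias_of> <http://www.w3.org/1999/02/22-rdf-syntax-ns#type> <http://www.w3.org/2002/07/owl#SymmetricProperty> .
...
```

Loaded into any SPARQL engine, "which occurrences have taxonomic
information?" becomes:

```sparql
PREFIX bsc: <http://biscicol.org/terms/biscicol.owl#>
PREFIX dwc: <http://rs.tdwg.org/dwc/terms/>
SELECT ?occurrence WHERE {
  ?occurrence bsc:related_to ?taxon .
  ?occurrence a dwc:Occurrence .
  ?taxon a dwc:Taxon
}
```

which returns exactly the 10 occurrence IRIs whose rows carried taxon
values. The exported `example-mapping.json` can be edited (for instance
to add a `ro:derives_from` relation) and replayed:

```sh
Rscript inst/cli/dwctriplify.R example.zip -m example-mapping.json -s turtle -o example.ttl
```

Automated mode and a replay of its own exported mapping are guaranteed to
produce identical graphs.

## Command line

`inst/cli/dwctriplify.R` (installed under the package's `cli/` directory)
is a thin Rscript front end:

```
dwctriplify.R [options] input [input ...]
  -f/--format {auto,csv,dwca,xlsx,ods}   -s/--serialization {ntriples,turtle,dot}
  -o/--out PATH        -m/--mapping FILE     --write-mapping FILE
  --base-uri URI       --class-graph FILE    --vocabulary FILE
  --strict             --no-prelude          -v/--verbose
```

Exit status is 0 iff the conversion succeeded; reports and warnings go to
standard error, data only to files.

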