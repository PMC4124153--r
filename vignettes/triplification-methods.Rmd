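---
title: "From tabular biodiversity data to RDF: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tabular biodiversity data to RDF: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwctriplify)
```

## The problem

Most digitized biodiversity data live in flat tables: a Darwin Core
Archive (DwC-A), a CSV export, a spreadsheet. Each row typically mixes
information about several different kinds of things — an occurrence
record, the collecting event, the place, the taxon, the identification —
and almost none of those implicit entities carry identifiers. That makes
the data hard to link across datasets and awkward to query at the level
of entities and relationships.

`dwctriplify` converts such tables into RDF. It detects which entity
classes a table describes, pulls each class out into its own deduplicated
instance table, constructs deterministic identifiers where none exist,
and emits typed triples connected by a deliberately small relationship
ontology. The output is standard N-Triples or Turtle (or Graphviz DOT for
visualization) that loads into any triple store and answers SPARQL
queries like *which occurrences have taxonomic information?* in three
lines.

## The vocabulary

The working vocabulary is a pinned snapshot of the Darwin Core term list
from the era before `dwc:MaterialSample` was added, shipped as a plain
TSV (`inst/extdata/dwc_terms.tsv`, columns: uri, kind, domain, label).
Three interpretive moves turn the raw term list into something usable for
linked data:

* The six DwC "categories" — Occurrence, Event, Location (from Dublin
  Core), GeologicalContext, Identification, Taxon — are treated as RDFS
  classes, and the per-class `...ID` terms (`occurrenceID`, `eventID`,
  ...) as the terms that denote instance identifiers for those classes.
* Each remaining term's `organizedInClass` assignment is read as the
  property's domain. This works for everything except the record-level
  terms; seven of those (`dcterms:type`, `institutionID`, `collectionID`,
  `institutionCode`, `collectionCode`, `ownerInstitutionCode`,
  `basisOfRecord`) in practice describe an occurrence record, so they are
  given the domain `dwc:Occurrence`. The rest stay domainless: they are
  kept in the vocabulary, excluded from automatic mapping, and usable
  through explicit attribute mappings (with a validation warning so the
  user knows the attachment point was their choice).
* Seven Dublin Core classes (Location, Agent, Image, MovingImage,
  PhysicalObject, Sound, Text) are included for biocollections data that
  goes beyond the core categories.

Column matching is case-insensitive on bare local names (real CSV headers
vary in case) but exact on full URIs, which are case-sensitive by
standard. A bare name matching two different namespaces is an explicit
ambiguity error rather than a silent pick.

Users can replace the snapshot with their own TSV (`--vocabulary`). An
RDFS/Turtle vocabulary file is *not* accepted as input — the tabular form
is the single supported interface, a deliberate simplification.

## The relationship ontology

Rather than wait for a full-featured biodiversity ontology, instance
linking uses four high-level properties, with OWL semantics declared so
reasoners can do the rest:

| property          | symmetric | transitive | reading                          |
|-------------------|-----------|------------|----------------------------------|
| `ro:derives_from` | no        | yes        | physical derivation              |
| `bsc:depends_on`  | no        | no         | existential dependence           |
| `bsc:alias_of`    | yes       | yes        | same thing, two identifiers      |
| `bsc:related_to`  | yes       | no         | non-dependent association        |

Only `depends_on` and `related_to` appear in the default class graph;
`derives_from` and `alias_of` are never applied automatically and are
available through hand-written relation mappings only.

The default class-to-class edge set connects: Occurrence `related_to`
Taxon, Identification `depends_on` Occurrence, Identification
`related_to` Taxon, Occurrence `depends_on` Event, Event `related_to`
Location, and Event `related_to` GeologicalContext. The first two edges
are the canonical examples of their properties; the remainder follow
standard Darwin Core usage (an occurrence is recorded at an event, events
are situated in a location and geological context, an identification
asserts a taxon). The set is a JSON config (`--class-graph`), so a
deployment can adjust edges without code changes. When a dataset has
Location or GeologicalContext columns but no Event columns, those classes
connect directly to the hub class with `related_to` — the intermediate
node the default edges assume simply does not exist in such data.

Two numerical/semantic choices are worth stating:

* **Direction normalization.** For symmetric properties one triple is
  emitted, in the direction the configured edge lists. Symmetry lives in
  the OWL declaration (`owl:SymmetricProperty` in the output prelude),
  not in materialized reverse triples; this halves triple counts and
  keeps output canonical.
* **`relation_closure()` is a test utility, not an emission step.** It
  computes the least fixpoint under symmetry and transitivity (boolean
  Floyd–Warshall per transitive property) and is checked against a naive
  rule-saturation oracle in the test suite. Note that the fixpoint of a
  symmetric-and-transitive property over `a–b–c` includes the reflexive
  pairs `(a,a)`, `(b,b)`, `(c,c)`: `a ~ b` and `b ~ a` compose.

## Normalization

Column analysis resolves each column to a vocabulary term (declared
DwC-A term URI first, header name as fallback) and thus to a class. Then,
per class present:

* rows are projected onto that class's columns; a row whose projection is
  entirely empty contributes no instance (whitespace-only cells count as
  empty throughout — this prevents vacuous literals);
* projections deduplicate on the explicit identifier if the class has an
  ID column, otherwise on the full tuple of literal values. Real-world
  archives are messy, so an identifier reused with
  *different* literal values is a warning (first-seen values win), not an
  error; `--strict` upgrades it. A row with literals but an empty
  explicit identifier is skipped with the same warning/strict behavior —
  there is no principled identity for such an instance;
* a link table records, per source row, the instance of each class the
  row contributed to. All relation emission is driven by this table, so
  co-occurrence in a source row is exactly what "linked" means.

Classes with no ID column get local integer identifiers, assigned
`1..n` in first-appearance order of the deduplicated tuples — a pure
function of input row order, which is what makes the whole pipeline
byte-deterministic. The synthesized column is named `localID`.

DwC-A extension tables (star schema) are normalized independently and
linked to the core's hub-class instances through the `coreid` join;
orphaned coreid values warn.

## Instance identifiers

Constructed identifiers concatenate
`table + "." + id_column + "_" + value`, percent-encode the result
(RFC 3986 unreserved set, uppercase hex, UTF-8 bytes), and append it to a
configurable base URI (default `http://example.org/id/`). The encoding
rule and the base are this package's documented choices: the
concatenation scheme itself guarantees only within-dataset uniqueness,
and no global identifiers are minted — that is explicitly out of scope.
Columns the user declares globally unique pass through verbatim and must
parse as absolute IRIs; anything else is an error naming the value.

Literals are plain: untyped, no language tags. Source cells are untyped
text, and inventing datatypes for, say, `decimalLatitude` would be a
semantic claim the data does not make. A datatype mapping layer is a
clean extension point.

## The four configuration steps and the mapping file

A conversion is fully described by four things: joins between tables,
entity mappings (table, identifier column, class, global-ID flag),
attribute mappings (column to literal property), and relation mappings
(entity pair plus one of the four properties). For DwC-As all four steps
are completed automatically; the resulting `mapping_config` can be saved
as versioned JSON, hand-edited, and replayed — automated mode and
mapping-file mode provably produce identical graphs when the mapping came
from automated mode on the same input. The JSON schema is this package's
own (keys: `version`, `base_uri`, `fingerprint`, `joins`, `entities`,
`attributes`, `relations`); it is not compatible with any database-to-RDF
mapping language, by design — a self-contained, documented format beats
an inherited one. The `fingerprint` (table and column names at build
time) triggers a warning when a mapping is replayed against a structurally
different dataset, instead of failing silently or mysteriously.

Validation is report-based: errors (dangling references, a non-relation
property in a relation mapping) block emission; domain mismatches and
domainless record-level terms are warnings, because mapping freely is a
legitimate user choice.

## Serialization

N-Triples output is sorted line-wise (byte order); Turtle is grouped by
subject in sorted order with `@prefix` declarations for the namespaces in
use. Both serializations of a graph are parse-equal, which the test suite
verifies with an independent RDF library, and repeated runs on the same
input are byte-identical — determinism is treated as a feature users can
diff on. The DOT export renders IRIs as prefixed-name ellipse nodes and
literals as box nodes, one edge per triple.

The emitted graph opens with an ontology prelude (the four properties
typed `owl:ObjectProperty` plus `owl:SymmetricProperty` /
`owl:TransitiveProperty` as applicable, 8 triples) so that downstream
reasoners see the semantics; `--no-prelude` suppresses it.

## The synthetic-data generator

`fixture_spec()` / `generate_dwca()` produce occurrence-core archives
with controlled structure: which classes have columns, which carry
explicit IDs, a per-class duplicate fraction (the share of filled rows
that repeat an earlier instance), and a per-class missing-cell fraction.
Values come from small fixed pools; the first literal column of each
class embeds the instance number, so distinct instances are distinct by
construction and every expected count — instances per class, links per
relation, literal cells, and the occurrence IRIs that should answer the
Taxon query — is computed *by construction* into a JSON manifest, not by
running the pipeline.

What the generator deliberately does not model: realistic value
distributions, quoting/encoding pathologies, multi-file extension
archives (those are exercised by hand-built fixtures in the tests), or
conflicting identifiers. Passing the grid therefore demonstrates
structural correctness of the pipeline — detection, deduplication,
identifier assignment, linking, serialization — not robustness to every
real-world archive's dirt.

Test problem sizes: the ground-truth grid runs `n_rows` of 0, 1, 25 and
500 with duplicate fractions 0 and 0.5; the closure property suite runs
1000 random graphs of up to 5 nodes and 6 edges; identifier construction
is exercised over 500 random fixtures. These sizes exercise every code
path (empty inputs, single rows, heavy duplication) while the whole suite
stays fast enough to run on every change.

## Known limitations

* No RDF/XML or JSON-LD output; no direct triple-store loading.
* No relational-database readers; the reader registry is the documented
  extension point (`register_reader()`), so a DB-backed reader can be
  added without touching existing code.
* Deduplication is exact; near-duplicates ("Boulder Creek" vs "boulder
  creek") stay distinct instances.
* The ODS reader is minimal (text cells of the sheet grid); unusual
  OpenDocument features (covered cells, repeated rows) are unsupported.
* Multi-gigabyte archives are out of scope: everything is in memory,
  desk-scale batch conversion is the target.
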