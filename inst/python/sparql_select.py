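"""Run a SPARQL SELECT query against an RDF file.

Usage: python sparql_select.py <rdf-file> <format: nt|turtle> <query-file>
Prints one result row per line (tab-separated term values).
"""
import sys

import rdflib


def main() -> int:
    rdf_path, fmt, query_path = sys.argv[1], sys.argv[2], sys.argv[3]
    g = rdflib.Graph()
    g.parse(rdf_path, format=fmt)
    with open(query_path, encoding="utf-8") as fh:
        query = fh.read()
    for row in g.query(query):
        print("\t".join(str(term) for term in row))
    return 0


if __name__ == "__main__":
    sys.exit(main())
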