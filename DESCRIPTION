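Package: ContextKG
Title: Context-Specific Biomedical Knowledge Graphs from Entity Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds context-specific, provenance-tracked biomedical
    knowledge graphs from plain lists of gene or metabolite identifiers or
    from a differential-expression result table. Input identifiers are
    harmonized onto canonical namespaces (Entrez for genes, UMLS for
    diseases, PubChem for compounds) through a pluggable mapping source;
    selected data-source annotators are run through an injectable
    transport and their typed assertions merged into a single property
    graph with a closed 18-type node vocabulary and 10-relation edge
    vocabulary, per-edge provenance, and query metadata. Graphs serialize
    to Cytoscape JSON, GraphML (round-trippable), and RDF Turtle with
    automatically generated SHACL shapes, and can be summarized, sliced
    into context subgraphs, and exported as labelled triple sets for
    graph machine learning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
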