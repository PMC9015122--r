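Package: pathsem
Title: Semantic Harmonization of Pathway Diagram Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts graphically drawn biological pathway diagrams (GPML, the
    WikiPathways drawing format) into a two-layer RDF-style graph: a graphical
    layer recording every drawn element, and a semantic layer holding only
    identifiable biological entities and their interactions, harmonized across
    the WikiPathways, MIM and SBGN arrowhead notations into a nine-class
    interaction hierarchy. Includes shape-based structural validation of the
    semantic layer, curation reports for unconverted elements, datanode and
    interaction statistics, and up-/downstream and enzyme-ordering queries
    over the resulting network. A seeded fixture generator produces GPML
    documents with known ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate:
    'vocab.R'
    'graph.R'
    'gpml-model.R'
    'gpml-io.R'
    'registry.R'
    'semantify.R'
    'shapes.R'
    'reporting.R'
    'network.R'
    'fixtures.R'
    'demo-pathways.R'
    'cli.R'
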