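Package: pathograph
Title: Graph-Based Representation and Analysis of Pathology Knowledge
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Typed graph representations of pathology knowledge: pathology
    entity graphs (entities, part-whole composition, pathological features and
    quantitative parameters), phenotype graphs (single-cell, multi-cell and
    quantitative phenotypic indicators), and staged differential-diagnosis
    graphs. Documents are serialized to and parsed from PathoML, an OWL-based
    markup (Turtle and RDF/XML dialects). Entity graphs are built automatically
    from polygon segmentation scenes (GeoJSON), with nuclear morphometrics
    (area, perimeter, roundness, shape factor, solidity) and membrane
    staining-extent measurement. Includes a quantitative HER2
    immunohistochemistry scorer driven by graph-pattern queries, and a
    structural subsumption reasoner for automatic histologic subtyping from
    diagnostic knowledge expressed as conjunctive existential concepts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    igraph,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
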