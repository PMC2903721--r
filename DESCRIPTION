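Package: rnakb
Title: RNA Structure Annotation and Knowledge-Graph Population
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Parses RNA three-dimensional structures in PDB format, annotates
    base pairs (Leontis-Westhof edges and Lemieux-Major sub-edges/faces), base
    stacks with adjacency and base-normal orientation qualities, ribose sugar
    puckers (envelope/twist, endo/exo) and glycosidic conformations (syn/anti),
    and populates an RDF-style knowledge graph that relates molecular structure
    files, structure models, molecules, residues, atoms and their qualities.
    Ships a bundled ontology catalog (classes, properties, sub-edge
    agglomeration axioms), a Manchester-syntax class-expression parser and a
    closed-world query evaluator with saturation (subclass, inverse, symmetric
    and transitive closure), plus generators for idealized A-form duplexes,
    constructed sugar-pucker rings and planned knowledge-graph fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    withr
Config/testthat/edition: 3
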