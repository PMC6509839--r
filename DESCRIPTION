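Package: cellgate
Title: Parsing and Ontology-Based Validation of Flow Cytometry Gating Definitions
Version: 0.1.0
Authors@R:
    person("cellgate", "maintainers", email = "cellgate@example.org", role = c("aut", "cre"))
Description: Tools for standardized reporting of flow-cytometry cell
    populations. Tokenizes gating-definition strings under per-center
    separator dialects, normalizes each gate to a canonical protein marker
    (via tiered, case-insensitive synonym lookup against a Protein
    Ontology-style catalog) or to a scatter/dye gate, and normalizes marker
    intensity labels (-, +, +-, +~, ++) to a preferred symbol set. Parses
    population names of the form "'CL label' & extras" against a Cell
    Ontology-style catalog, computes each cell type's inherited marker
    constraint closure from Manchester-style logical definitions
    (has/lacks_plasma_membrane_part), and cross-checks gating definitions
    against that closure to flag conflicts. Includes corpus-level match
    provenance summaries, a synthetic corpus generator with planted ground
    truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    stringi,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
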