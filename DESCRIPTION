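Package: groovescan
Title: Protein-DNA Minor Groove Contact and Width Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects amino acid residues contacting the DNA minor groove in 3D
    structures of protein-DNA complexes using a nearest-reference-atom rule,
    associates each contact with a dinucleotide step and its local minor groove
    width (cross-strand phosphate distance convention), classifies grooves as
    narrow, standard or wide, and computes interface composition, secondary
    structure, hydrogen-bond, GC-content and width-distribution statistics.
    Includes a fully ledgered synthetic structure generator (fiber-model A- and
    B-form duplexes, groove perturbations, planted probe residues) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
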