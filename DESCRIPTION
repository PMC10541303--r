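Package: npscreen
Title: Network-Pharmacology Screening of Herbal Compound Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An offline, file-based network-pharmacology screening pipeline
    for multi-herb compound libraries: QED drug-likeness scoring from eight
    physicochemical descriptors with oral-bioavailability gating, compound
    deduplication across herbs, intersection of predicted compound targets
    with disease-associated genes under a relevance-score cut, protein-protein
    interaction topology (degree, betweenness, closeness) for key-target
    selection, exact hypergeometric over-representation analysis with
    Benjamini-Hochberg adjustment, and assembly of the tripartite
    compound-target-pathway network with degree-based key-compound
    nomination. Includes monoisotopic-mass and adduct m/z arithmetic for
    mass-spectrometric identity checks, and a seeded synthetic-data generator
    that emulates every database input (compound descriptors, target
    predictions, disease genes, STRING-style interaction edges, GMT
    annotation sets) with planted ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
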