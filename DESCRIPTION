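Package: klsite
Title: Site-Wise Functional Divergence by Symmetric Kullback-Leibler Information
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects alignment sites under different functional constraints
    between two groups of homologous proteins. Each alignment column is scored
    by the symmetric Kullback-Leibler information between the two groups'
    site-specific amino acid compositions, estimated with Henikoff-Henikoff
    position-based sequence weights and PSI-BLAST-style data-dependent
    pseudocounts (ungapped lambda solved by Newton-Raphson). Top-scoring sites
    are mapped onto a reference receptor structure, projected onto the
    extracellular-intracellular axis of the helix bundle, and tested for
    spatial bias with Welch t-tests; a pocket-enrichment ratio test compares
    site sets across comparisons. Includes generators for synthetic two-group
    alignments with planted divergent sites and parametric toy helical-bundle
    structures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
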