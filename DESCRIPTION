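Package: sweetR
Title: Sequence Analysis of SWEET and SemiSWEET Sugar Transporters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative sequence analysis of the SWEET/SemiSWEET
    sugar-transporter family: PQ-loop motif detection and hydropathy-based
    transmembrane-helix screening, protein sequence similarity networks
    with e-value thresholding and cluster labelling, repeat-unit
    architecture classification (SemiSWEET, SWEET, extraSWEET, superSWEET)
    with gene duplication/fusion evidence, progressive multiple alignment
    with column conservation and mutual-information coevolution profiling,
    neighbour-joining trees with bootstrap support, and MM/PBSA
    binding-energy bookkeeping. Includes a seeded synthetic-family
    generator with planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    ape,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
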