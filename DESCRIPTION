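Package: mitochar
Title: Characterization of Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the desk-scale characterization of annotated circular
    mitochondrial genomes, modelled on the analyses routinely reported for
    newly sequenced invertebrate mitogenomes: strand- and wrap-aware feature
    extraction, base composition with AT/GC strand-skew statistics, codon
    usage and relative synonymous codon usage (RSCU) under the invertebrate
    mitochondrial genetic code, an intergenic spacer/overlap census with
    gene-order signatures, constrained cloverleaf folding of mitochondrial
    tRNAs (including D-armless topologies), and a distance-based
    neighbor-joining phylogeny stage with supermatrix construction, outgroup
    rooting and monophyly queries. A seeded synthetic-genome generator with a
    ground-truth manifest makes every stage testable offline, and the
    packaged gene layout, composition and codon-usage reference tables for
    the shrimp Caridina mariae reproduce that study system by default.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
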