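Package: metaBLUP
Title: Metafounder Single-Step Genomic BLUP for Structured Breeding Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-step genomic BLUP (ssGBLUP/HBLUP) for multi-population
    breeding programs with explicit base-population structure. Estimates the
    metafounder relationship matrix Gamma from descendant genotypes by
    generalized least squares, builds pedigree, genomic and combined
    relationship matrices with and without metafounders or unknown-parent
    groups, solves the mixed-model equations for the standard site + additive
    + full-sib-family model, and evaluates predictions by the LR
    cross-validation method (accuracy, stability, dispersion, bias). A
    seed-deterministic population simulator with divergent base populations,
    gene dropping and multi-site phenotypes provides full-truth test data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
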