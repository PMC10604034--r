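Package: mitocomp
Title: Comparative Characterization of Vertebrate Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated vertebrate (teleost)
    mitochondrial genomes: gene-architecture accounting (intergenic spacers,
    overlaps, strand usage, gene order and breakpoint distances), partition-wise
    nucleotide composition with AT/GC skew statistics, start/stop codon
    classification including incomplete stops, template-based tRNA cloverleaf
    folding with Watson-Crick/wobble pair labelling, control-region analytics
    (tandem repeats, conserved sequence blocks, variable sites), Kimura
    two-parameter distances, neighbor-joining trees, GTR+Gamma likelihoods with
    BIC model ranking, and relative-rate divergence dating under fossil
    calibrations. A seeded synthetic-mitogenome and sequence-evolution
    generator provides ground-truth data for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
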