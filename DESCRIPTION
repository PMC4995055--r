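Package: mitocomp
Title: Comparative Analytics for Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy analytics for annotated circular mitochondrial genomes,
    built around the whitefly (Aleyrodidae) mitogenome architecture:
    feature-table accounting (gene sizes, intergenic spacers, overlaps,
    strand census), base composition and strand-asymmetry (AT/GC skew)
    statistics, codon usage and RSCU under the invertebrate mitochondrial
    code, Nei-Gojobori (NG86) Ka/Ks selection screening with Jukes-Cantor
    correction, signed circular gene-order comparison via breakpoint
    distances with a neighbor-joining distance tree, and dissection of
    control-region structure (tandem-repeat arrays, stem-loops,
    homopolymer runs). A fully specified synthetic-mitogenome simulator
    provides planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    ape,
    Biostrings,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
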