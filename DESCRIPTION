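Package: asyntraits
Title: Trait Dissimilarity and Interannual Abundance Asynchrony
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links pairwise species trait dissimilarity to interannual
    abundance asynchrony in species communities. Computes asynchrony
    matrices from collated annual abundance indices, Gower trait
    dissimilarity for mixed binary/continuous traits with
    equal-group-contribution weighting, patristic distances from
    phylogenies (with species-complex collapsing), and simple and partial
    Mantel permutation tests with bootstrap confidence intervals. A
    synthetic-data module generates phylogenies, traits evolved on them,
    and trait-driven abundance panels with analytically known expected
    asynchrony, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    igraph,
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
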