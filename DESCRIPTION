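Package: ervography
Title: Comparative Genomics of Endogenous Retrovirus Colonization in Primate Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct the colonization history of an endogenous
    retrovirus (ERV) group across a clade of host genomes: seed-and-extend
    discovery of ERV loci, structural classification into proviruses,
    L1-mediated processed pseudogenes and solitary LTRs, flank-anchored
    mapping of orthologous insertions across species, Dollo-style assignment
    of insertion events to branches of a dated species tree, LTR-LTR
    recombination inference, majority-rule consensus building, CpG-stripped
    p-distances, Kimura 2-parameter distances, neighbor-joining trees with
    bootstrap support, and windowed dot-plots. A forward simulator plants
    insertion histories with full ground truth so every stage can be
    validated against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
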