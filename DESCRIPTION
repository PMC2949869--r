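Package: mtphylogeo
Title: Mitochondrial Phylogeography of Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mitochondrial-DNA phylogeography of geographically
    structured populations: haplotype collapsing and polymorphic-site
    classification from aligned sequences, gene and nucleotide diversity with
    Nei's variance estimators, Tajima's D and Fu's Fs neutrality tests with
    coalescent-simulated significance, hierarchical analysis of molecular
    variance (AMOVA) with permutation tests and a spatial simulated-annealing
    partition search (SAMOVA), median-joining haplotype networks, F84/UPGMA
    gene-tree reconstruction, a structured-coalescent gene-tree simulator on
    population trees, and the Slatkin-Maddison minimum-migration parsimony
    test of allopatric divergence. Includes a synthetic-data generator that
    emulates a continent-wide cytochrome-b survey of the lowland tapir
    (Tapirus terrestris) so that every pipeline stage can be exercised on
    data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
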