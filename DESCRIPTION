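Package: markerdiv
Title: Dominant-Marker Diversity Analysis for Binary Band Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for genetic diversity analysis of gel-scored dominant
    molecular markers (RAPD, ISSR, SCoT). Classifies loci as monomorphic,
    polymorphic or unique, computes per-primer and per-system polymorphism
    percentages and a RAPD/SCoT fidelity index, builds Dice (also Jaccard
    and simple-matching) genotype similarity matrices, clusters genotypes
    with WPGMA/UPGMA into ultrametric dendrograms with Newick export,
    cophenetic distances and k-cluster extraction, and analyses the
    companion morphological data with one-way ANOVA, Fisher's LSD pairwise
    comparisons and a compact letter display. A seeded synthetic-data
    module generates band matrices with exact locus-class counts and
    normally distributed trait tables, including a five-genotype kalanchoe
    fixture, so the whole pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    vegan
Config/testthat/edition: 3
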