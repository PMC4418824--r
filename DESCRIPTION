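Package: oxtkit
Title: Ligand-Receptor Coevolution and Phylogeny-Trait Association for
    the Primate Oxytocin System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying genetic diversity in a peptide
    hormone and its G protein-coupled receptor across a clade, built
    around the oxytocin (OXT) / oxytocin-receptor (OXTR) system in
    primates.  Computes pairwise nucleotide distance matrices under
    standard substitution corrections (p, JC69, K2P, Tamura 3-parameter,
    with optional gamma rate heterogeneity), quantifies ligand-receptor
    coevolution by mirror-tree matrix correlation with a Mantel
    permutation null, implements the monophyletic-clade (MC)
    phylogeny-trait association statistic over a tree sample with a
    tip-permutation null, profiles peptide physicochemistry
    (Kyte-Doolittle GRAVY, isoelectric point by charge bisection), and
    classifies amino-acid substitutions as radical or conservative by
    polarity, charge and volume categories with per-domain substitution
    proportions.  A synthetic-data generator (Yule trees, sequence
    evolution by continuous-time Markov chains, binary traits with
    tunable phylogenetic signal, pseudo tree samples) makes every stage
    testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    phangorn,
    seqinr,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
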