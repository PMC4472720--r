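Package: statbin
Title: Weighted Statistical Binning for Coalescent-Based Species Tree Estimation
Version: 0.1.0
Authors@R:
    person("Statbin", "Developers", email = "statbin@example.org", role = c("aut", "cre"))
Description: Tools for statistical binning of gene trees prior to
    coalescent-based species tree estimation. Gene trees with bootstrap
    support are tested for pairwise combinability under a support
    threshold, an incompatibility graph is built and colored with a
    balanced greedy (Brelaz-style) heuristic, per-bin supergene
    alignments are assembled, and supergene trees are weighted by bin
    size so that the supergene tree distribution tracks the gene tree
    distribution. Includes multispecies-coalescent gene tree simulation,
    GTR+Gamma sequence simulation, neighbor-joining gene tree estimation
    with site bootstrapping, greedy consensus and R* (plurality rooted
    triplet) species tree summaries with multi-locus bootstrapping, an
    exhaustive fully partitioned Jukes-Cantor maximum likelihood solver
    for small taxon sets, and evaluation statistics (missing-branch
    rate, branch-length ratios, per-triplet Jensen-Shannon divergence,
    support-ordered edge quality curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
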