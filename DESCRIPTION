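Package: evodiverse
Title: Multi-Objective Evolutionary Sampling of Protein Conformation Decoys
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A memetic multi-objective evolutionary algorithm for template-free
    generation of protein conformation decoys. Conformations are represented by
    backbone dihedral angles over a coarse-grained (centroid) chain and sampled
    by molecular fragment replacement. Offspring are refined by greedy local
    search under a staged coarse-grained energy model, and survival is decided
    by non-dominated sorting with crowding distance over a three-objective
    decomposition of the energy (short-range hydrogen bonds, long-range
    hydrogen bonds, everything else). Includes total-energy and Pareto-rank
    baseline selectors, structure-comparison metrics against a known native
    (CA lRMSD, TM-score, GDT_TS), head-to-head contingency construction with
    Fisher and Barnard exact tests, and synthetic toy targets plus fragment
    libraries so the whole pipeline runs without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    seqinr,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
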