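Package: megasynth
Title: Simulation and Search Tools for Modular Megasynthase Assembly Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A rule-based simulator for type I modular polyketide synthase
    (PKS), nonribosomal peptide synthetase (NRPS) and hybrid biosynthetic
    gene clusters. Given a cluster's domain architecture it predicts every
    carrier-bound chemical intermediate and the released product, applies
    the structure-informed repair rule that inactivates reductive domains
    lacking their prerequisite reaction, encodes architectures as Unicode
    strings for Levenshtein-distance cluster search with edit scripts as
    chimera-design instructions, and ranks predicted intermediates against
    a target molecule by counted atom-pair Tanimoto chemosimilarity.
    Clusters are interchanged as schema-validated JSON; substrate tables
    are editable TSV files; chemistry is backed by OpenBabel via ChemmineOB.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
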