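Package: editcode
Title: Structure-Aware Modeling of A-to-I RNA Editing from Saturation
    Mutagenesis Libraries
Version: 0.1.0
Authors@R: person("editcode", "Authors", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the cis-regulation of adenosine-to-inosine
    (A-to-I) RNA editing from saturation-mutagenesis variant libraries of
    hairpin substrates. Provides a built-in secondary-structure engine
    (minimum free energy folding, McCaskill partition function and base-pair
    probabilities under hard constraints, and a constrained-ensemble
    probability of the catalytically active conformation), bpRNA-style
    structural element annotation with tree-edit structure similarity,
    variant library handling (designed mutation enumeration, read-based
    editing quantification, library Z-score standardization, and a
    sequence-by-structure mutation taxonomy), per-mutated-base featurization,
    gradient-boosted-tree modeling with leakage-free position-based splits
    and Shapley-value attribution, a synthetic-data generator, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    ape,
    Biostrings,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
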