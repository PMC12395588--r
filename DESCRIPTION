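Package: lgtsurvey
Title: Gene-Tree Incongruence Surveys for Detecting Lateral Gene Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveying topological incongruence across sets of
    per-marker gene trees to detect lateral gene transfer (LGT) between a
    focal clade (such as Eukarya) and target prokaryotic lineages (such as
    the Asgard archaeal orders). Provides sister-group classification of
    the focal clade in every tree, nodal-distance profiling between clades,
    a simulation-based near-excess test for bimodal distance profiles,
    lineage-affinity censuses, per-marker transfer-direction inference, a
    ground-truthed gene-tree simulator built on subtree-prune-and-regraft
    transfer events, and a scanner for lineage-specific insertions in
    protein alignments with a Fitch parsimony check of insertion histories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    phangorn,
    Biostrings,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
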