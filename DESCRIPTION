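Package: fetrflp
Title: T-RFLP Fingerprinting and Bioenergetics of Iron-Reducing Enrichment Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying dissimilatory Fe(III)-reducing enrichment
    communities from terminal restriction fragment length polymorphism
    (T-RFLP) data. Predicts terminal restriction fragment lengths by in
    silico digestion of dual-end-labelled 16S rRNA amplicons (MspI, HaeIII,
    HhaI), cleans raw electropherogram peak tables (size-window export,
    iterative signal/noise discrimination, duplicate-digest consensus,
    cross-sample binning), assigns binned fragments to phylotypes by a
    six-of-six signature match, and analyses the resulting community
    matrices with Bray-Curtis dissimilarity, UPGMA clustering, cophenetic
    validation and Kruskal-Wallis factor tests. Companion geochemistry
    functions compute percent Fe(III) reduced across
    mineral x carbon x dilution enrichment grids and activity-corrected
    Gibbs free-energy yields for iron- and sulfate-reducing redox couples.
    A fully seeded synthetic-data generator plants restriction signatures
    into amplicon sequences, simulates noisy duplicate electropherograms
    and emulates the Fe-reduction response surface, so every stage of the
    pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    vegan,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
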