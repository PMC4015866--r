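Package: mirgrain
Title: Small RNA Profiling of Developing Cereal Grains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for small RNA sequencing of developing
    cereal grains: adapter trimming and read collapsing, classification of
    reads against non-coding RNA catalogs, conserved microRNA family
    assignment, exact two-library count tests for differential expression
    with TPM normalization, hierarchical clustering of fold-change
    trajectories into developmental archetypes, hairpin-based discovery of
    novel microRNAs from a transcript set, and complementarity-based target
    prediction. A ground-truthed synthetic data generator emulates staged
    grain-filling libraries so every stage of the pipeline can be validated
    against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    S4Vectors,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
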