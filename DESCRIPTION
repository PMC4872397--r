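Package: spareatlas
Title: SPARE-Style Brain-Age Indices, Advanced-Aging Groups and Voxel-Wise Atrophy Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds machine-learning indices of brain aging and Alzheimer-like
    atrophy from voxel-wise gray-matter volumetric maps (SPARE-BA and SPARE-AD:
    linear support-vector-machine decision values trained on young-vs-old or
    AD-vs-control reference groups, with uncontaminated jackknife scoring of
    training members), defines advanced-brain-aging (ABA) and resilient (RA)
    groups from age-residualized z-scores, maps group atrophy differences with
    voxel-wise Student t-tests under Benjamini-Hochberg false-discovery-rate
    control, partitions the overlap of aging- and AD-associated patterns,
    computes a weighted-allele-sum Alzheimer polygenic risk score, and fits
    sex-stratified multivariable risk-factor models. A seeded synthetic-cohort
    generator plants known atrophy geometry, risk-factor effects and genotype
    structure so that every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
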