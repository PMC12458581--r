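Package: laasp
Title: Aging-Trajectory Plasticity Analysis for Liver Multi-Omic Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies liver aging-associated plasticity (LAAsP) genes from
    longitudinal expression contrasts, quantifies how early-life exposure
    signatures overlap and attenuate or accelerate their normal aging
    trajectories, maps differential histone-mark peaks to promoters and merged
    enhancer anchors with direction-concordance classification, and scores
    transcriptomes with summed z-score signature activity. Ships a synthetic
    multi-omic study generator with planted ground truth so every stage of the
    pipeline has a recovery target, plus hypergeometric over-representation,
    preranked gene-set enrichment, and a permutation null for pathway-set
    overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
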