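Package: epifold
Title: Enhancer-Promoter Interaction Prediction with Hilbert-Curve Sequence Encoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes fixed-length enhancer and promoter DNA sequences onto
    Hilbert space-filling-curve grids, trains a two-branch convolutional
    classifier of enhancer-promoter interaction (EPI), supports two
    cross-cell-line transfer-learning protocols (fine-tuning with and
    without convolutional-layer freezing), attributes predictions back to
    sequence k-mers through gradient-weighted class-activation maps pushed
    through the inverse Hilbert map, and computes a cross-cell-line EPI
    sequence-overlap statistic. Includes a ground-truth-aware synthetic
    multi-cell-line EPI data generator, class-imbalance handling by
    over-/under-sampling, and AUPR-centred evaluation for imbalanced
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    withr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    GenomicRanges,
    rtracklayer,
    png,
    yaml,
    jsonlite,
    optparse
Config/testthat/edition: 3
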