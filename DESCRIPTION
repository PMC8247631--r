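Package: nucseg
Title: Style-Aware Scaffolding for Nucleus Instance Segmentation Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating nucleus instance segmentation
    pipelines on 2D microscopy images: size-normalizing preprocessing that
    rescales images to a common nucleus diameter, appearance ("style")
    clustering of unannotated images, style-matched synthetic training-data
    generation from a nucleus shape database and a parametric shape simulator,
    a six-parameter morphological post-processing chain with genetic-algorithm
    tuning, and the full Data Science Bowl 2018 evaluation suite (object
    matching over IoU thresholds, DSB score, mAP/mAR/mF1, mask cross-entropy
    loss, and a missed/false/split/merge error taxonomy). Segmentation
    backends are pluggable; a classical threshold-plus-watershed backend and a
    deterministic toy-image simulator are included so the whole pipeline runs
    on a desktop CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    nnet,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
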