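Package: phenosynth
Title: Fruit Phenotype Quantification, Source-Domain Selection, and
    Auto-Labeled Orchard Scene Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building auto-labeled fruit detection datasets
    without manual annotation. Quantifies fruit phenotypes from
    transparent-background sprite images with Fourier boundary shape
    descriptors, CIELAB interval color histograms, and rotation-invariant
    uniform local binary pattern texture histograms; fuses the three
    pairwise feature-distance matrices into a common two-dimensional
    feature space (scale normalization, classical multidimensional
    scaling, principal-component fusion) and selects optimal
    source-domain datasets as density-cluster medoids; composites
    rule-governed synthetic orchard scenes with per-instance masks,
    polygons, tight bounding boxes and a bounded occlusion ratio; and
    refines detector pseudo-labels with an adaptive Otsu-style
    confidence threshold self-learning loop plus a precision, recall and
    average-precision evaluator. A procedural fixture generator
    (sprites, leaves, layered backgrounds, mock detector) makes every
    stage reproducible and testable offline.
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
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
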