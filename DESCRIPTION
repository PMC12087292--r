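Package: CytoVote
Title: Ensemble Convolutional Classification of Single-Cell Morphology by
    Majority Voting
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies stained single-cell microscopy crops by combining
    independently fine-tuned convolutional backbones through plurality
    ("majority-rule") voting. Provides NTSC luminance grayscale conversion
    with percentile contrast stretching, a labeled image datastore built
    from class-per-directory trees, stratified train/validation/test
    splitting, transfer-learning style fine-tuning of registered backbones
    (frozen convolutional trunk, trainable dense block and softmax head,
    SGDM/Adam/RMSProp optimizers with early stopping), vote tallying and
    tie-aware plurality fusion, confusion-chart evaluation, and a seeded
    synthetic generator of Giemsa-Wright-style single-cell images with a
    controllable class-separation parameter for benchmarking every stage
    without access to curated slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
biocViews: Classification, SingleCell, CellBiology, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
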