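Package: meddistill
Title: Knowledge Distillation from Frozen Vision Backbones for Compact
    Medical Image Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains compact convolutional classifiers for MedMNIST-style
    28x28 medical images by distilling temperature-softened predictive
    distributions from a frozen, linear-probed vision backbone. Implements
    the temperature softmax, the t^2-scaled Kullback-Leibler distillation
    loss mixed with a hard-label cross-entropy (or binary cross-entropy)
    term, phase-1 linear probing of the frozen teacher, phase-2 student
    distillation with a multi-step learning-rate schedule and early
    stopping, MedMNIST AUC/ACC evaluation conventions for binary,
    multi-class, multi-label and ordinal tasks, NPZ dataset input/output,
    a synthetic class-conditional image generator for fully offline
    testing, 2-D feature embeddings and class-evidence heatmaps, and a
    command-line interface over all stages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
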