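Package: dscnl
Title: Dual-Stage Clean-Sample Selection for Class-Incremental Learning
    with Noisy Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Class-incremental image classification under symmetric label
    noise. Implements a dual-stage clean-sample selection framework: a
    per-class two-component Gaussian mixture over historical prediction
    confidences filters clean training subsets, a test-time-augmentation
    vote sampler scores uncertainty to fill a class-balanced replay
    buffer, and a mixup-based soft-replay objective consolidates old
    knowledge robustly.  Ships a synthetic labelled-image stream
    generator, symmetric noise injection, disjoint task splitting, NPZ
    dataset I/O, a small trainable softmax backbone, and evaluation
    metrics (final average accuracy, selection purity, noise reduction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    zip
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
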