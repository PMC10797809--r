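Package: evidfuse
Title: Dempster-Shafer Evidence Fusion with Softmax Remapping for
    Classifier Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decision-level fusion of multi-classifier probability outputs
    with Dempster-Shafer evidence theory. Implements the classical
    combination rule with conflict-factor diagnostics, and a softmax
    (exponential-normalization) remapping of basic probability assignments
    that eliminates the classical rule's conflict paradoxes (complete
    conflict, zero trust, one trust, high conflict) before combination.
    Includes per-sample batch fusion of classifier probability matrices,
    multiclass evaluation metrics (precision, recall, specificity, F1,
    Cohen's kappa, one-vs-rest AUC, percentile-bootstrap intervals), a
    sixfold RGB image augmentation scheme (resize, random rotation,
    mirroring, channel permutation), seeded synthetic generators for
    classifier outputs and test images, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    caret,
    e1071,
    jpeg,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
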