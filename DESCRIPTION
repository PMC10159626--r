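Package: wormmem
Title: Analysis of Associative-Memory Coding in Compact Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing calcium-imaging recordings and
    chemotaxis behaviour from C. elegans associative-learning experiments.
    Provides ground-state normalization of fluorescence traces, a pairwise
    group-comparison design with positive false discovery rate (pFDR)
    adjustment, population decoding of training condition from multi-neuron
    activity, a linear-combination model of interneuron activity, PCA-based
    filtering of experience-component activity differences, locomotion
    metrics (deviation angle, speed, reversals) from worm tracks, and an
    agent-based simulator of the two-choice chemotaxis assay. Includes
    synthetic-data generators with planted ground truth so every stage can
    be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
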