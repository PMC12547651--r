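Package: nocilabel
Title: Pharmacological Labeling and Baseline-Phenotype Classification of
    Nociceptors in Multi-Well MEA Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for identifying presumptive nociceptors in heterogeneous
    sensory-neuron cultures recorded on multi-well microelectrode arrays.
    Implements kernel-density labeling of agonist-evoked changes in max-bin
    mean firing rate against an untreated pseudo-treatment null (Gaussian
    kernel, Silverman rule-of-thumb bandwidth, percentile thresholding),
    baseline spike-train phenotyping (mean firing rate, inter-spike-interval
    coefficient of variation, adaptive-coincidence pairwise spike
    synchronization), imbalance-aware classification of the labels from the
    baseline phenotype (a random-undersampling boosted decision-tree
    ensemble plus reference classifiers), rank-based group comparisons, and
    a gamma-renewal synthetic spike-train generator with planted responder
    subpopulations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    nnet,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
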