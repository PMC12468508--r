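Package: qeegnl
Title: Nonlinear Complexity Analysis of Quantitative EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-channel nonlinear complexity features for resting-state
    multichannel EEG: kernel-density-based Renyi entropy, Tsallis entropy
    with an adjustable entropic index, and Lempel-Ziv (LZ76) complexity of
    the mean-thresholded binary sequence. Includes a synthetic 19-channel
    EEG cohort generator (band-limited oscillations plus 1/f noise with
    group-dependent broadband share), artifact-based epoch rejection and
    common-length trimming, channel-wise Mann-Whitney U testing with
    Bonferroni correction and an entropic-index sensitivity grid,
    information-gain / gain-ratio attribute ranking with MDLP
    discretization, a five-model cross-validated classification suite with
    decision-rule extraction for neurofeedback thresholds, and exact t-SNE
    embeddings with silhouette-based cluster-separation scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    nnet,
    randomForest,
    rpart,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
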