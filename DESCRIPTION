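Package: bloodPairs
Title: Gene-Pair Disease Signatures from Blood Transcriptomes with
    Collection-Tube Bias Suppression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers self-normalizing gene-pair panels that predict
    disease from whole-blood expression profiles while suppressing
    systematic biases such as those introduced by EDTA versus PAXgene
    blood collection tubes. Provides replicate-based probe-set
    stability filtering, AUROC screening of within-sample ratio and sum
    pair features, suppressor-pair detection for confounder
    cancellation, replication-based group balancing with controlled
    Gaussian noise, Monte-Carlo search over pair combinations scored by
    a logistic model, one-against-all multi-disease evaluation under
    iterated stratified 2-fold cross-validation, and a synthetic cohort
    generator with planted tube biases, disease effects and shared
    confounders for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
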