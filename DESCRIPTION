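Package: comet
Title: Clinical and Omics Multimodal Analysis Enhanced with Transfer Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements COMET, a transfer-learning framework for analysing
    small omics cohorts with the help of large coded electronic health record
    (EHR) databases. Longitudinal concept codes are grouped into day
    "sentences", embedded with skip-gram word2vec, summarised into daily mean
    embeddings and encoded with a recurrent (gated recurrent unit) or
    transformer encoder pretrained on an EHR-only cohort. The frozen encoder
    is transferred into a three-branch multimodal network (EHR, omics, joint)
    whose branch predictions are mixed by a bias-free linear combiner, for
    continuous or binary outcome prediction. Also provides prior-informed
    ridge and logistic regression baselines that shrink coefficients toward
    pretrained solutions, a patient-grouped repeated train/test/validation
    evaluation protocol with averaged validation predictions, a seeded
    synthetic cohort generator with a shared latent state linking code
    emission, analyte abundance and outcome, and an interpretation suite
    (integrated gradients, latent-analyte alignment, correlation maps,
    intermediate-node performance, function-space trajectories).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
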