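Package: cbptsdscreen
Title: Screening for Childbirth-Related PTSD from Birth Narratives
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for screening childbirth-related
    post-traumatic stress disorder (CB-PTSD) from free-text childbirth
    narratives. Implements PCL-5 total scoring with a provisional cutoff of
    31, minimum-length filtering, class balancing by down-sampling, pairwise
    data augmentation with Hadamard-product embedding features, a small
    feedforward similarity classifier trained with Adam and early stopping,
    repeated-resampling evaluation with label-only (stepped) ROC metrics,
    and zero-/few-shot chat-prompt baselines against an abstract, mockable
    backend. A synthetic-data module generates corpora and class-separated
    embeddings so the whole pipeline runs offline and deterministically.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
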