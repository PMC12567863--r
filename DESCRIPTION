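Package: sleeprec
Title: Personalized Sleep Recommendations from Wearable Lifelogs and Bed Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for personalized sleep recommendation from multimodal
    lifelog data: a synthetic cohort generator with planted group structure,
    preprocessing of multirate bed-sensor signals (Hampel filtering, zero-phase
    band-pass, hidden-Markov posture smoothing, spectral respiration
    estimation), nightly user profiling with a fixed 68-dimension feature
    schema, silhouette-driven K-means clustering on PCA scores, cluster-based
    similar-user matching, feedback-based collaborative re-ranking, a small
    multilayer-perceptron ranker trained with a Bayesian Personalized Ranking
    plus Huber objective, and a top-K ranking evaluation harness (mAP, F1)
    with grouped user splits and ablations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    cluster,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
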