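Package: spikecast
Title: Multimodal Few-Shot Prediction of Anthesis in Individual Wheat Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts whether an individual wheat plant will reach anthesis
    within a critical number of days by fusing a wheat-head image with a
    90-day weather history and a 6-day forecast. A pairwise Siamese
    comparator (shared image + weather feature extractor with fully
    connected or transformer comparative heads) is trained by meta-learning
    on labelled image-weather pairs, then deployed in new environments by
    anchor-based one-shot or five-shot inference. Includes photo-degree-day
    weather features, video frame selection by Laplacian variance,
    quota-constrained pair sampling, a ten-cycle evaluation protocol with F1
    scoring, and a fully synthetic benchmark generator (procedural head
    imagery plus a cumulative photo-degree-day flowering model) so the whole
    pipeline runs without external data. All networks and the training loop
    are implemented in R matrix algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    png,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
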