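Package: moodconn
Title: Behavioural Partial Least Squares for Connectivity-Mood Covariance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links session-wise functional-connectivity edge patterns to
    multi-scale mood ratings with behavioural partial least squares (SVD of
    the standardized cross-correlation matrix), and provides the full
    inferential apparatus around the decomposition: permutation tests on
    singular values, bootstrap-ratio reliability of edge and scale weights,
    split-half pattern stability, and out-of-sample cross-validation.
    Network-level characterization includes regional contribution maps,
    community-block statistics with label-permuting null models, and
    per-session segregation-integration measures (weighted modularity under
    the configuration model, system segregation) correlated with behaviour.
    Synthetic multi-session generators with planted low-rank cross-covariance
    and planted modular AR(1) time-series structure provide ground truth for
    every stage.
License: MIT
Encoding: UTF-8
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
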