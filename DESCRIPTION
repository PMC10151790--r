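Package: strfeast
Title: Event-Driven Auditory Feature Extraction with a CAR-FAC Cochlea and FEAST
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An event-driven auditory front end for spike-based audio analysis.
    A software CAR-FAC cochlear filterbank (cascade of asymmetric resonators
    with optional fast-acting compression, inner-hair-cell detection and
    lateral inhibition) drives leaky integrate-and-fire neurons that encode
    per-channel amplitude as asynchronous spike events. Exponential
    time-surface event contexts (1-D temporal and multi-scale 2-D
    spectrotemporal) are extracted around each event and fed to FEAST
    (Feature Extraction using Adaptive Selection Thresholds), an unsupervised
    competitive learner with per-neuron adaptive cosine-similarity thresholds.
    Feature maps are time-binned into fixed-length vectors and evaluated with
    a cross-validated linear classifier. A seeded synthetic-speech generator
    (harmonic sources, formant trajectories, syllabic envelopes) makes the
    whole pipeline testable without licensed corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    Matrix,
    glmnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
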