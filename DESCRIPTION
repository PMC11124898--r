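Package: enose
Title: Electronic-Nose Spoilage Detection with Class-Overlap Discretization
    and an Ensemble Convolutional Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for metal-oxide-semiconductor (MOS)
    electronic-nose sensor arrays aimed at early detection of rotting
    produce under ambient-gas interference. Provides a synthetic
    sensor-array simulator with adsorption/desorption response kinetics,
    relative-conductivity baseline correction, time- and frequency-domain
    curve features, mutual-information-based feature selection with an
    SVM recursive-elimination wrapper, supervised class-overlap feature
    discretization with one-hot re-encoding, a stacked ensemble of
    one-dimensional convolutional networks fused by a convolutional
    meta-learner, and a repeated stratified evaluation harness with
    classical baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    nnet,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
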