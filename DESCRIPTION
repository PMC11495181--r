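Package: gaspnet
Title: Spike-Train Connectivity and Motor-Pattern Analysis for Brainstem
    Respiratory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of simultaneously recorded brainstem neuron spike
    trains and respiratory motor signals. Provides phase-normalized
    respiratory cycle-triggered histograms with a two-test
    respiratory-modulation classification, pairwise cross-correlogram
    screening against gamma interspike-interval surrogate nulls with a
    detectability index and false discovery rate control, spike-triggered
    averaging of rectified nerve signals, motor-pattern epoch segmentation
    of a phrenic-like signal under hypoxia (augmentation, apneusis, apnea,
    gasping), gasp and blood-pressure step detection, and assembly of
    directed correlation feature maps. A coupled point-process generator
    with known ground truth supports parameter- and structure-recovery
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
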