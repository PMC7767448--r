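Package: snnerp
Title: Brain-Inspired Spiking Neural Network Modelling of Event-Related Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for modelling multichannel event-related potential
    (ERP) data with a brain-inspired spiking neural network. ERP epochs are
    converted to ternary spike trains by threshold-based encoding, fed into a
    three-dimensional spatially mapped reservoir of leaky integrate-and-fire
    neurons with distance-dependent small-world connectivity, and learned with
    spike-timing-dependent plasticity. A dynamic evolving spiking neural
    network (deSNN) output layer with rank-order initialisation classifies
    samples under leave-one-out cross-validation, alongside conventional
    baselines. Trained reservoirs are summarised as regional connection-weight
    tables analysed with repeated-measures ANOVA (Greenhouse-Geisser
    corrected) and Kendall's tau correlations against psychometric scores.
    Includes a synthetic auditory-oddball ERP cohort generator with plantable
    group-by-time effects for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    car,
    e1071,
    nnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
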