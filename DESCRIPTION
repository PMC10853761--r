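Package: dynsort
Title: Spike Sorting of Electrically Evoked Neural Activity with Linear
    Dynamical Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies which neurons fired after electrical stimulation on a
    dense multi-electrode array despite the stimulation artifact. Each
    neuron's electrical image and the artifact are modeled as linear
    state-space systems driven by short input templates; the models are
    composed under superposition into an aggregate system, and a windowed
    regularized least-squares input estimator inverts the aggregate model to
    recover which templates (hence which spikes) produced the measured
    post-stimulus voltages, with corrupted electrodes such as the stimulating
    electrode excluded. Includes a synthetic-data generator for array
    geometry, propagating biphasic spikes, amplitude-scaled artifacts and
    logistic activation, plus activation-curve fitting, 50% threshold
    extraction, K-fold artifact validation and threshold comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    rhdf5,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
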