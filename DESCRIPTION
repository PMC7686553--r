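Package: pfcquant
Title: Layer-Resolved Neuronal Activation and Microglia-Neuron Interaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of layer-specific neuronal activation and
    microglia-neuron interaction in cortical fluorescence microscopy, together
    with the behavioural and neurochemical readouts that accompany such
    studies. Provides dual-threshold (area and mean gray value) classification
    of c-Fos immunostained nuclei with cortical layer assignment, binarization
    and topology-preserving skeletonization of the microglial network,
    soma-centered 2D Sholl analysis of non-isolated skeletons with an identity
    (y = x) baseline, neuron-centered 2D and 3D Sholl analysis of the
    microglial membrane volume, soma-contact fractions, Y-maze spontaneous
    alternation scoring, open-field distance/velocity/rotation metrics, and
    superfusion fractional-release arithmetic. A synthetic-data module
    generates multi-channel cortical image stacks, trajectories and release
    series with exhaustive ground truth so that every stage of the pipeline is
    testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    jsonlite,
    optparse
Config/testthat/edition: 3
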