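Package: fcvae
Title: Counterfactual Functional Connectivity Analysis with Variational
    Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Normative ("counterfactual") analysis of resting-state
    functional connectivity from parcellated BOLD time series.  Trains
    variational autoencoders (convolutional, recurrent, and parallel
    hybrid encoder/decoder families) and their phenotype-conditioned
    variants on windowed parcel-by-time matrices, generates
    neurotypical-like reconstructions of neurodivergent scans by flipping
    the diagnostic condition, and localizes under- and over-connectivity
    between five canonical resting-state networks with Welch t
    divergence maps.  Includes a generative simulator of parcellated
    BOLD cohorts with known network coupling structure, sliding-window
    augmentation, reconstruction and latent-space evaluation metrics, a
    sex-bias functional-connectivity similarity score, chord-diagram
    rendering, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    tools,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
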