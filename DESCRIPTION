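Package: scentmap
Title: Inverse Retrieval of Odorant Mass Spectra from Scent Impressions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts which odorant mass spectra realize a desired scent
    impression by inverting the usual sensing-to-perception direction.
    Electron-ionization mass spectra (unit-mass m/z 51-262) are compressed
    with a five-layer sparse autoencoder, the 50-dimensional latent codes
    are organized on a 30x20 hexagonal self-organizing map, neurons are
    labeled with binary odor descriptors, and inverse mapping of a labeled
    neuron returns the co-clustered molecules and their spectra. Includes
    mass-spectral cosine similarity with head-to-tail comparison data,
    principal-component closeness checks, exact right-tailed one-proportion
    binomial statistics for duo-trio sensory panels, a synthetic odorant
    dataset generator for end-to-end validation, and a command-line
    interface over the pipeline stages.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
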