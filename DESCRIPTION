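Package: paintquant
Title: Absolute Labeling Efficiency and Dimerization Quantification for
    DNA-PAINT Localization Data
Version: 0.1.0
Authors@R:
    person("paintquant", "developers", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for absolute quantification of binder labeling
    efficiency and of labeling-efficiency-corrected dimerization
    fractions from single-molecule localization microscopy (DNA-PAINT /
    Exchange-PAINT) data. Localization clouds are clustered into
    molecule centers, cross nearest-neighbor distances between a
    reference and a target channel are compared to complete-spatial-
    randomness monomer/dimer mixture simulations, and population
    proportions are estimated by least-squares histogram fitting with
    bootstrap uncertainty quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    FNN,
    jsonlite,
    optparse,
    rhdf5,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
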