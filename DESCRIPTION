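Package: costsep
Title: Multiresolution Coherent Spatiotemporal Scale Separation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Unsupervised decomposition of multiscale spatiotemporal signals
    (neural field potentials, geophysical fields) into coherent frequency
    bands. Sliding windows of the data are fit with variable-projection
    optimized dynamic mode decomposition (DMD) models at a hierarchy of
    window lengths; eigenvalues are clustered into frequency bands locally
    per level and globally across levels, and each band's coherent
    spatiotemporal contribution is reconstructed with window-center
    weighting. Includes a synthetic multiscale field generator with exact
    ground truth, model persistence, band export, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'snapshot.R'
    'optdmd.R'
    'level.R'
    'global.R'
    'driver.R'
    'synthetic.R'
    'io.R'
    'cli.R'
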