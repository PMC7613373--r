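Package: cncmap
Title: Hybrid Retrieval of Canopy Nitrogen Content from Imaging Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a hybrid workflow that converts hyperspectral canopy
    reflectance into aboveground canopy nitrogen content (CNC) maps with
    per-pixel uncertainty. A protein-resolving leaf optical properties model
    coupled to a four-stream canopy radiative transfer model simulates a
    labelled training database; spectra are compressed by principal component
    analysis; a Euclidean-distance-based diversity active-learning loop tunes
    the training set against validation data; Gaussian process regression
    provides predictive means and variances; and image cubes are processed
    into trait maps with coefficient-of-variation uncertainty masking.
    Includes sensor band-grid handling with Gaussian spectral response
    resampling, a spike-removal/window-exclusion/spline-gap-filling cleaning
    chain for spaceborne spectra, and synthetic generators for field
    campaigns, non-vegetated spectral libraries and ground-truthed scenes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    kernlab,
    optparse
Config/testthat/edition: 3
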