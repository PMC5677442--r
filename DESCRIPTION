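Package: moundscan
Title: Detection of Termite Mounds in UAV Hyperspectral Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for automatic detection of pre-existing
    termite mounds in visible/near-infrared (385-1000 nm) hyperspectral
    imagery acquired from unmanned aerial vehicles. Provides ENVI-style
    cube input/output and region-of-interest handling, reflectance recovery
    against a white-reference illuminant, material spectra library
    construction by deterministic-annealing clustering, per-pixel support
    vector machine material classification, and a two-layer contour
    detector that matches eroded-soil core shapes against mound templates
    by their log-scaled Hu moment invariants and confirms each candidate
    by the proximity of a surrounding light-grass ring. Includes a
    synthetic hyperspectral scene generator with exact ground truth and a
    TP/FN/FP accuracy evaluation module.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
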