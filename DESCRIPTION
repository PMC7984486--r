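Package: redspr
Title: Stoichiometric CT Calibration and Proton Stopping-Power Ratio
    Uncertainty Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying how human-tissue chemical composition
    affects the estimation of kilovoltage CT numbers and proton stopping-power
    ratios (SPR) from relative electron density (RED).  Implements the
    stoichiometric CT calibration model (photoelectric, coherent and Compton
    terms), Bragg-additivity mean excitation energies and the Bethe-type SPR
    ratio for reference human tissues; builds segmented linear calibration
    curves from RED to CT number and from RED to SPR; propagates Gaussian
    perturbations of elemental weights through the pipeline to separate
    systematic from statistical estimation uncertainty; and compares the
    RED-linearity of kilovoltage and megavoltage CT numbers with a narrow-beam
    photon attenuation model.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
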