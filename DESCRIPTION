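Package: rootsip
Title: Spectral Induced Polarization Analysis for In-Situ Root Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for multi-frequency complex resistivity (spectral
    induced polarization) imaging of crop root systems. Provides containers for
    frequency-sampled complex resistivity spectra on 2D tomogram grids,
    four-electrode measurement scheme generation with geometric factors and the
    associated raw-data quality filters, Debye decomposition of cell spectra
    into chargeability and relaxation-time distributions (including a
    low-frequency-restricted variant), the electrical root index (ERI) as a
    spectral dispersion measure of root presence, root-zone volume-weighted
    trait aggregation, Schwarz-relation translation of relaxation times into
    cell-scale diameters, and a synthetic field generator that emulates soil,
    maize and sugar-beet polarization signatures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    withr
Config/testthat/edition: 3
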