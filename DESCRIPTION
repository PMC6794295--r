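Package: simsTransfer
Title: Single-Cell nanoSIMS Stable-Isotope Probing of Carbon and
    Nitrogen Transfer from Diazotrophs to Epibionts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the transfer of freshly fixed carbon and nitrogen
    from filamentous diazotrophic cyanobacteria to their attached epibionts
    from single-cell nanoSIMS isotope imaging. Provides drift correction and
    accumulation of multi-plane secondary-ion count stacks, per-cell isotope
    ratios with Poisson counting-statistics uncertainties, detection-limit
    filtering, conversion of isotope enrichment to relative activities,
    cellular assimilation and substrate-based growth rates, and the
    partitioning of total fixed C and N between a cyanobacterial cell and
    its epibionts. Companion calculators cover bulk isotope mass-balance
    fixation rates and 33P radiotracer phosphate uptake with decay and
    control corrections. A synthetic-data module simulates every input
    class (ion-count image stacks with drift, radiotracer time series,
    bulk incubations) with known ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    tiff,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
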