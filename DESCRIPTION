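Package: imprintscreen
Title: Tiered Newborn-Screening Workflow for Chromosome 15 Imprinting Disorders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for population newborn screening of
    Prader-Willi, Angelman and Dup15q syndromes from SNRPN promoter methylation.
    Provides a synthetic newborn-cohort generator with parent-of-origin
    methylation and copy-number profiles, a first-tier methylation quantifier
    for bisulfite-PCR high-resolution melt curves (derivative peak-area
    deconvolution with spiked-standard calibration and per-plate control
    correction), population threshold calling, second-tier droplet digital PCR
    methylation confirmation with Poisson occupancy correction, relative
    standard-curve copy-number qPCR classification, third-tier low-coverage
    whole-genome-sequencing copy-number segmentation with breakpoint and
    subtype assignment, and screening performance statistics with exact
    binomial confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
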