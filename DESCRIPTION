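Package: alidose
Title: Aerosol Dosimetry and Dose-Response Analysis for Air-Liquid
    Interface Nanotoxicology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for computing delivered particle doses in air-liquid
    interface (ALI) cell exposure experiments and for the tiered
    statistical analysis of the resulting toxicological responses.
    Represents SMPS number size distributions, fits the mass-mobility
    power law of fractal aggregates measured by DMA-APM, summarizes TEM
    primary-particle samples (Sauter diameter, specific surface area),
    estimates electrostatic deposition efficiency from SEM wafer particle
    counts, and combines these into number, mass, and surface-area doses
    per square centimetre of cell culture.  A three-tier exposure and
    dose-response statistics stage (pooled tests, per-material tests,
    linear dose-response regression with ANCOVA) and a synthetic-data
    generator for every input complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    pracma,
    yaml,
    png,
    tiff,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
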