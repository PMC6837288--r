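Package: altadapt
Title: Demographically Informed Selection Scans, Cline Fitting and
    Gene-Set Expression Shifts for Altitude Adaptation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic tools for detecting spatially varying
    selection along elevational gradients. Implements per-site
    Weir-Cockerham FST and the population branch statistic (PBS) from
    VCF genotypes, a structured-coalescent simulator with population
    splits and two migration-rate classes for building neutral PBS null
    distributions, folded two-dimensional site-frequency-spectrum
    composite-likelihood demographic fitting, Metropolis-Hastings
    fitting of equilibrium sigmoid allele-frequency clines over
    elevation, and a permutation-calibrated Kolmogorov-Smirnov test for
    concerted expression shifts of candidate gene sets between genotype
    groups. Includes synthetic-data generators for every input so the
    full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    edgeR,
    graphics,
    jsonlite,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
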