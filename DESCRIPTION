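Package: episphere
Title: Spherical Evolutionary Multi-Objective Detection of Multi-Locus
    SNP Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects multi-locus SNP interactions (epistasis) in
    case-control genotype panels with a spherical evolutionary search
    guided by a decomposition-based bi-objective fitness combining the
    Bayesian-network K2 score and the likelihood-ratio (G) statistic.
    Includes a GAMETES-style penetrance-table simulator for disease
    models with and without marginal effects, G-test and multifactor
    dimensionality reduction (MDR) validation of candidate
    combinations, detection-power and confusion metrics, and export of
    interaction networks in SIF format.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
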