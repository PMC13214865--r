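Package: hcpval
Title: Total-Error Validation of Untargeted Host Cell Protein Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical machinery for ICH Q2(R2)-style total-error validation
    of label-free LC-MS/MS quantification of host cell proteins (HCPs) in
    biotherapeutics. Covers theoretical tryptic digestion and deterministic
    parsimony protein inference, peptide filtering and Hi3 (top-3) absolute
    quantification against spiked standards, entrapment-based empirical false
    discovery proportion estimation with bootstrap and Wilson uncertainty,
    weighted least-squares calibration with HC3-robust inference, one-way
    random-effects variance decomposition with Welch-Satterthwaite effective
    degrees of freedom, beta-expectation and 95/95 content tolerance intervals
    with acceptance decisions and validated-range determination,
    abundance-stratified total-error profiling with abundance-aware
    quantitation limits, cross-software and cross-platform agreement
    statistics (Deming, Lin's CCC, Bland-Altman), system-suitability
    evaluation with Phase I individuals-moving-range control charts, and a
    synthetic-data generator reproducing the hierarchical validation design
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    sandwich,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
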