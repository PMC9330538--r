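Package: ramanpheno
Title: Label-Free Raman Phenotyping of Tumor Metastatic Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for label-free Raman spectral phenotyping of
    tumors along the metastatic cascade. Provides a synthetic-cohort
    generator with known ground truth, fingerprint-region preprocessing
    (wavenumber calibration, iterative polynomial fluorescence-background
    subtraction, median filtering, vector normalization), non-negativity
    constrained MCR-ALS decomposition into pure-component-like constituent
    spectra, leave-one-mouse-out random-forest classification with
    class-equalized ensemble voting, out-of-bag permutation importance with
    non-neighboring spectral-marker selection, and nonparametric group
    statistics (Wilcoxon rank-sum tests with Wendt rank-biserial effect
    sizes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
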