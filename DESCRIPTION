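Package: methvar
Title: Robust Testing of Differential Variability in DNA Methylation Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies CpG sites whose methylation variability, rather than
    mean level, differs between groups of samples. The test regresses
    leverage-corrected absolute (or squared) deviations of M values from the
    group means on the experimental design and moderates the resulting
    t-statistics with an empirical Bayes variance prior, making it robust to
    the outliers that break the classical F and Bartlett tests. Includes
    transformations between beta values, M values and raw intensities,
    rowwise F and Bartlett baseline tests, a hierarchical simulation engine
    with outlier and differential-variability injection, and evaluation
    metrics (type I error rates, FDR, power, ROC).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), limma, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
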