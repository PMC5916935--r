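Package: mlacdiff
Title: Differential Glycoform Expression from Multi-Lectin Affinity
    Fractionated Serum Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantitative analysis of serum glycoproteomic data in which
    protein glycoforms are separated by multi-lectin affinity
    chromatography (unbound flow-through, AAL-bound core-fucosylated and
    PHA-bound highly-branched fractions) and quantified as heavy/light
    isotope ratios of cysteine-labeled peptides against a common
    reference pool.  Provides a seeded synthetic-cohort generator,
    elution-profile isotope-pair quantitation with a precursor
    mass-accuracy filter, identification-confidence filtering and
    peptide-to-protein rollup per lectin fraction and globally, per-sample
    log2 median-centering, permutation Welch t-tests with permutation-based
    false discovery rate estimation, and classification of cross-fraction
    significance patterns, together with an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
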