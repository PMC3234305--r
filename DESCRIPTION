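Package: qfish
Title: Database-Free Clustering and Spectral-Count Quantification of Tandem MS Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters tandem mass spectrometry (MS/MS) spectra by direct
    pairwise comparison of moving-window-average peak profiles, without any
    database or spectral-library search. Spectra are grouped in two stages
    (precursor m/z agreement within a pairwise tolerance, then single-linkage
    clustering on the Pearson correlation of smoothed profiles), peptides are
    quantified by spectral counts per cluster, clusterings are validated with
    a permutation-based false clustering rate computed from retention-time
    coefficients of variation, and differentially abundant peptide clusters
    between two sample groups are detected with a beta-binomial likelihood
    ratio test with Benjamini-Hochberg correction. Includes a ground-truthed
    synthetic MS/MS run generator for end-to-end validation, MGF input, and
    TSV outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
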