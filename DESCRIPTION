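Package: motifdecon
Title: Supervised Motif Deconvolution of Multi-Allelic MHC Immunopeptidomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Assigns mass-spectrometry eluted ligands from multi-allelic MHC
    class I and class II immunopeptidome samples to their most likely HLA
    restriction using percentile-rank scores, with a trash cluster for
    co-immunoprecipitated contaminants. Provides a position-specific scoring
    matrix (PSSM) backend with empirical percentile-rank calibration against
    random natural peptides, readers and writers for peptide lists, sample
    sheets and long-format prediction tables, motif reporting
    (core frequency matrices, Kullback-Leibler sequence-logo data, length
    distributions, cross-sample consistency matrices), a benchmarking
    protocol based on confusion matrices and Matthews correlation
    coefficients with bootstrap confidence intervals, and a seeded synthetic
    immunopeptidome generator with ground-truth labels, scrambled-peptide
    null sets and k-mer overlap filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
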