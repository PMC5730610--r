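Package: radfst
Title: F-Statistics, Completeness Filtering and Missing-Data Bias for RAD-Seq Genotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for missing-data-aware population-genetic analysis of
    reduced-representation (RAD-seq) SNP panels and microsatellite data.
    Provides a diploid multi-population genotype container with readers for
    VCF, genepop and a plain TSV dialect; the locus-filtering regime used in
    RAD studies (single SNP per tag, minor-allele-frequency threshold, and a
    gradient of locus-completeness cutoffs yielding a family of nested
    datasets); sample-size-corrected Nei-Chesser gene diversities and F-statistics
    plus the Weir-Cockerham theta estimator, both tolerant of missing
    genotypes; percentile bootstrap confidence intervals over loci and
    locus-subsampling experiments that separate the effect of locus count from
    that of missingness; genotype principal component analysis; and a
    synthetic-data module simulating island-model panels at a chosen F_ST with
    RAD-style missingness, including restriction-site allelic dropout, so the
    bias of F-statistics under completeness filtering can be studied in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
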