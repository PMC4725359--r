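Package: dysbiome
Title: Paired-Site Skin Microbiome Dysbiosis Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired lesional/non-lesional 16S
    taxa-abundance profiles: alpha-diversity and evenness panels (Chao-1,
    Fisher's alpha, Shannon, Simpson, Good's coverage, rarefaction,
    successive relative-contribution differences), core-taxa calling by
    abundance/prevalence thresholds, a bootstrapped Wilcoxon rank-sum
    differential-abundance procedure with Benjamini-Hochberg correction and
    retention-fraction filtering, and per-class microbial co-occurrence
    networks built from tie-aware Spearman correlations of rank-normalized
    abundances, with degree-threshold hub analysis and cross-class network
    comparison. Includes a Dirichlet-multinomial synthetic-data generator
    emulating paired skin-site communities with subject-dominant signatures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
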