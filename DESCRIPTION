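Package: introflow
Title: Introgression Scans, Demographic Inference and Gene-Flow Direction
    Tests for Two-Species Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and characterization of interspecific introgression
    from multi-sample SNP data: Patterson's D (ABBA-BABA) with weighted
    block-jackknife significance, windowed f_dM scans, the f3 admixture
    statistic, windowed diversity and differentiation statistics (pi, Dxy,
    Hudson's FST, Tajima's D, Fu and Li's tests, LD decay), NG86 Ka/Ks with
    molecular-clock conversion, joint-SFS composite-likelihood fitting of
    two-population gene-flow models, and Bayes-factor direction-of-flow
    model choice via thermodynamic integration with Gauss-Legendre
    quadrature. Includes a structured-coalescent simulator (population
    splits, admixture pulses, epoch migration, infinite-sites mutation,
    RAD-seq-like degradation) that serves both as the test-data source and
    as the simulation engine for demographic inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
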