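Package: mqtlkit
Title: Family-Based Metabolite QTL Analysis with NMR Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for metabolite quantitative trait locus (mQTL)
    studies in family-based cohorts. Quantifies metabolites from paired 1D
    NMR spectra by deconvoluting the well-resolved J-resolved (JRES)
    projection into mixed Gauss-Lorentz (pseudo-Voigt) peaks and fitting the
    convoluted CPMG spectrum with a non-negative linear model; estimates
    heritability and household (sibship) effects by REML under a polygenic
    model with a pedigree kinship matrix; runs a kinship-aware mixed-model
    score-test GWAS with metabolome-wide multiple-testing correction,
    mode-of-inheritance scanning and analytic power; and fine-maps coding
    variants against lead GWAS SNPs by reciprocal conditional association.
    Ships a synthetic-data generator (pedigrees, genotypes with local LD,
    heritable phenotypes, paired CPMG/JRES spectra) so the whole pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    methods,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
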