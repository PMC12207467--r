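Package: partbias
Title: Participation Bias in Heritability and Genetic Correlation Estimates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the distortion of SNP heritability and genetic correlation
    estimates caused by selective study participation under a liability-threshold
    model, and adjusts participant-only estimates back to the population scale.
    Provides closed-form expressions for the "apparent" (selected-sample)
    heritability, cross-phenotype genetic correlation and participation-phenotype
    genetic correlation; the inverse adjustment chain driven by a participation
    GWAS, the participation rate, and phenotype mean shifts; a minimal LD score
    regression with block-jackknife standard errors; a Monte Carlo oracle for
    truncated multivariate normal moments; and a genotype-level simulator with
    block-wise autoregressive linkage disequilibrium for validating the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
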