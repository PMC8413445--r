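Package: wgbsqtl
Title: Methylation QTL Mapping and Genetic DMR Analysis for Whole-Genome
    Bisulfite Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for sequencing-based methylation
    quantitative trait locus (meQTL) analysis: simulation of whole-genome
    bisulfite sequencing (WGBS) count matrices with additive SNP effects,
    coverage-weighted local-likelihood smoothing of per-site methylation
    fractions, windowed cis-meQTL scanning by covariate-adjusted linear
    regression with genome-wide FDR-equivalent p-value cutoffs, clustering
    of genotype-associated cytosines into genetic differentially methylated
    regions (gDMRs), Storey pi0/pi1 cross-dataset sharing, methylation
    mediation of expression QTLs by coefficient attenuation, empirical-Bayes
    moderated-t differential methylation, and per-site SNP heritability with
    simplified stratified LD-score regression for annotation enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    knitr,
    limma,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
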