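Package: coxscan
Title: Time-to-Event GWAS with Left-Truncated Cox Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-SNP association scans for EHR-linked cohorts using Cox
    proportional-hazards regression under the counting-process formulation
    (left truncation and right censoring), a logistic-regression comparator
    with restricted-cubic-spline age adjustment, and the sequential
    logistic-then-Cox testing strategy. Includes delayed-entry Kaplan-Meier
    curves, genotype quality control (MAF, call rate, exact Hardy-Weinberg
    test), genomic-inflation and LD-block sensitivity evaluation, PLINK and
    TSV input/output, and a simulation framework for measuring power and
    type-I error of both methods under Cox and logistic generative models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    splines,
    jsonlite,
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
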