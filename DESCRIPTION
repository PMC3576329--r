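Package: mdcnv
Title: De Novo Copy Number Variant Detection in Case-Parent Trios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects de novo copy number variants (CNVs) in case-parent
    trios genotyped on SNP arrays. Computes the per-marker minimum
    distance between offspring and parental log R ratios, a univariate
    statistic that cancels technical variation (probe effects, genomic
    waves) shared within a trio, segments it by circular binary
    segmentation with a permutation test, and classifies each segment by
    maximum a posteriori estimation over the 121 biologically plausible
    trio copy-number states using robust mixture emission models for log
    R ratios and B allele frequencies and a Mendelian model of CNV
    transmission. Includes a trio simulator with known truth and an
    evaluation harness (marker-level false positive/negative counts,
    feature detection rates, concordance at the top of ranked lists).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
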