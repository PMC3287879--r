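Package: crocr
Title: Risk Prediction on Common and Rare Variants with Collapsing ROC Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Likelihood-ratio based risk prediction for case-control genotype
    data containing both common and rare variants. Implements the forward ROC
    (FROC) approach, which greedily selects predictor loci to maximize the area
    under the likelihood-ratio-ordered ROC curve with cross-validated choice of
    model size, and the collapsing ROC (CROC) approach, which first collapses
    rare variants into pseudo-common carrier indicators through a multistage
    greedy collapsing procedure and then runs forward selection over common and
    pseudo-common variants. Includes a synthetic case-control genotype
    simulator (Hardy-Weinberg genotypes, logistic liability) for calibration
    and recovery experiments, readers for VCF and delimited genotype formats,
    JSON model serialization, and a command-line interface.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
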