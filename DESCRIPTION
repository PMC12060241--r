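Package: midrangeqc
Title: Post-Imputation Quality Control for GWAS with the Midrange Filter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-imputation quality control for case-control genome-wide
    association studies. Aggregates significant SNPs into linkage-disequilibrium
    "spikes" by physical proximity and classifies whole spikes as true or false
    association signals with the Midrange Filter, which combines two
    imputation-quality thresholds with the disagreement between the dosage and
    best-guess genotype formats. Includes per-SNP imputation-quality measures
    (IMPUTE info, MaCH R2, a Beagle-style dosage R2, surrogate Iam/hiQ scores)
    computed separately per cohort group, a logistic-regression association
    scan in both genotype formats, confusion and ROC evaluation of
    quality-based filters, and a seedable synthetic case-control cohort
    simulator with haplotype-pool LD, array-scaffold deletion, and surrogate
    imputation for end-to-end testing without external data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
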