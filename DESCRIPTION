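Package: stableselect
Title: Stable SNP Feature Selection for Case/Control Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Heritability-based feature selection for genome-wide association
    studies of binary traits. SNPs are ranked by their per-feature
    contribution to explained phenotypic variation in a ridge-regularized
    linear regression, nested feature subsets are scored with a linear-kernel
    support vector machine under balanced cross-validation splits, and a
    Youden-index curve is cut at its first local maximum to select a
    candidate set. Repeating the whole procedure over many replications
    yields a per-SNP support count from which stable sets are drawn.
    Includes PLINK-style text genotype readers, variant quality control
    (missingness, minor allele frequency, Hardy-Weinberg, windowed LD
    pruning), a synthetic case/control cohort simulator with a
    phenotype-shuffling null control, per-SNP logistic and contingency-table
    association tests, predictivity evaluation (F1, AUC), and a histogram
    rule for selecting non-neutral polygenic-score weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
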