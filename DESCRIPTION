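Package: lipgs
Title: Polygenic Scoring of Lithium Treatment Response in Bipolar Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for building and evaluating a polygenic
    score of lithium treatment response from ALDA-scale phenotypes and
    genome-wide SNP data. Implements ALDA phenotype derivation with the
    standard inclusion and exclusion rules, pre- and post-imputation genotype
    quality control (including an exact Hardy-Weinberg test and cross-cohort
    merging), covariate-adjusted per-variant association scans, posterior SNP
    effect estimation under a continuous-shrinkage prior by Gibbs sampling on
    summary statistics with block linkage-disequilibrium references, five-fold
    leave-one-group-out cross-fitting to remove discovery-target circularity,
    logistic and two-limit Tobit association models with decile stratification
    and incremental pseudo-R2, and gene-based multi-marker tests with pathway
    overrepresentation analysis. A seeded synthetic-cohort generator emulating
    the statistical structure of lithium pharmacogenomic studies makes every
    stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
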