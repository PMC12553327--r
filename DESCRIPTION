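Package: forestGRS
Title: Random-Forest Genetic Risk Scores with Tuned Clumping and
    Thresholding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructs genetic risk scores (GRS) for binary traits with
    probability-machine random forests over SNP genotypes. Implements
    ctRF (joint grid-search tuning of the LD-clumping r-squared cutoff
    and the p-value threshold inside the forest pipeline), the cRF, tRF
    and oRF ablations, wRF (association-strength-weighted sampling of
    split candidates), and the classical additive clumping-and-
    thresholding score (oCT) as a baseline. Association p-values can
    come from external GWAS summary statistics (base data) or from the
    target training samples. Includes readers for PLINK 1 binary and
    VCF genotypes, a blockwise-LD genotype and epistatic-phenotype
    simulator covering five causal-architecture scenarios, and an
    evaluation harness (Nagelkerke R-squared, AUC, train/test splits,
    5-fold cross-validation, replicated experiments).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    Rcpp,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    ranger
Config/testthat/edition: 3
RoxygenNote: 7.3.3
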