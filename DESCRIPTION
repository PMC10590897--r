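Package: mlgwas
Title: Machine-Learning GWAS Feature Selection for Ordinal Herbicide-Damage Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature-selection pipeline for genome-wide association on ordinal
    field damage ratings, as used to classify soybean tolerance to off-target
    dicamba exposure. Plot-level 1-4 damage scores from multi-environment
    trials are adjusted to per-genotype least-squares means under a REML
    mixed model and binned into tolerance classes. SNP dosages are scored by
    partial-least-squares Variable Importance in Projection (VIP), filtered
    at a VIP cutoff, pruned for pairwise correlation, and fed to a forward
    stepwise selection loop over cross-validated Random Forest and radial
    support vector machine classifiers, recording per-iteration confusion
    metrics and an overfitting curve. A synthetic-data module simulates
    LD-blocked genotypes and multi-environment ordinal phenotypes with
    planted QTL so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    e1071,
    randomForest,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    lmerTest,
    emmeans
Config/testthat/edition: 3
RoxygenNote: 7.3.3
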