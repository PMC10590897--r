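#!/usr/bin/env Rscript
# Stage 2: adjust plot ratings to per-genotype means and tolerance classes.
#
# Fits the REML mixed model (genotype fixed; environment, replicate within
# environment, and GxE random) and classifies genotypes as tolerant
# (adjusted score <= 2), moderate (<= 3) or susceptible (> 3).

suppressMessages(library(mlgwas))

ratings <- read.csv("scratch/sim/ratings.csv", stringsAsFactors = FALSE)
out_dir <- "results/adjust"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

message("fitting the mixed model on ", nrow(ratings), " plot ratings ...")
adj <- fit_adjusted_means(ratings)
write_adjusted(adj, file.path(out_dir, "adjusted_phenotypes.csv"),
               file.path(out_dir, "variance_components.txt"))

message("variance components:")
print(round(attr(adj, "varcomp"), 4))
mix <- table(adj$tolerance_class)
message("tolerance class mix:")
print(mix)
message(sprintf("(%s)", paste(sprintf("%s %.1f%%", names(mix),
                                      100 * mix / sum(mix)), collapse = ", ")))
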