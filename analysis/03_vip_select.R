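#!/usr/bin/env Rscript
# Stage 3: PLS/VIP scoring, VIP >= 2.0 threshold, |r| >= 0.7 pruning.
#
# Fits PLS of the adjusted damage scores on all SNP dosages (components
# chosen by 10-fold CV under the one-standard-error rule), computes VIP
# scores, applies the VIP >= 2.0 cutoff and the greedy descending-VIP
# correlation pruning — producing the SNP funnel that feeds the classifiers.

suppressMessages(library(mlgwas))

geno <- read_genotypes("scratch/sim/dosages.csv", "dosage",
                       meta_path = "scratch/sim/snp_meta.tsv")
adj <- read.csv("results/adjust/adjusted_phenotypes.csv", stringsAsFactors = FALSE)
adj <- adj[match(rownames(geno$dosages), adj$genotype_id), ]
out_dir <- "results/select"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

geno <- filter_maf(geno, 0.05)
X <- impute_mean(geno)
message("fitting PLS on ", nrow(X), " x ", ncol(X), " ...")
fit <- fit_pls(X, adj$adjusted_score, max_components = 10, cv_folds = 10,
               seed = 1)
message("components chosen by CV: ", fit$n_components,
        sprintf(" (%.1f%% of response SS explained)",
                100 * sum(fit$y_variance_explained)))

vips <- compute_vip(fit, geno$snp_meta)
message(sprintf("mean VIP %.3f, range [%.3f, %.3f]; mean squared VIP %.6f",
                mean(vips$vip), min(vips$vip), max(vips$vip),
                mean(vips$vip^2)))

thresholded <- threshold_vip(vips, 2.0)
pruned <- prune_correlated(X, vips, 0.7, snp_subset = thresholded)
message(sprintf("SNP funnel: %d -> %d (VIP >= 2.0) -> %d (|r| < 0.7)",
                ncol(X), length(thresholded), length(pruned)))

write.csv(vip_report_table(vips, thresholded, pruned),
          file.path(out_dir, "vip_table.csv"), row.names = FALSE)
writeLines(pruned, file.path(out_dir, "selected_snps.txt"))
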