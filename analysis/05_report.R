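#!/usr/bin/env Rscript
# Stage 5: comparator single-marker scan and the consolidated report bundle.
#
# Runs the plain per-SNP regression scan (LOD = -log10 p, flag at LOD > 4),
# checks how the scan and the VIP track agree on the planted QTL, and
# renders the full report bundle (VIP Manhattan table, stepwise traces,
# overfitting curves, scan table, pooled confusion matrix of the best RF
# subset).

suppressMessages(library(mlgwas))

geno <- read_genotypes("scratch/sim/dosages.csv", "dosage",
                       meta_path = "scratch/sim/snp_meta.tsv")
adj <- read.csv("results/adjust/adjusted_phenotypes.csv", stringsAsFactors = FALSE)
adj <- adj[match(rownames(geno$dosages), adj$genotype_id), ]
vips_tab <- read.csv("results/select/vip_table.csv", stringsAsFactors = FALSE)
truth_qtl <- read.csv("results/sim/planted_qtl.csv", stringsAsFactors = FALSE)

X <- impute_mean(geno)
message("single-marker scan over ", ncol(X), " SNPs ...")
scan <- single_marker_scan(geno, adj$adjusted_score)
message(sum(scan$flagged), " SNPs flagged at LOD > 4.0")
hit <- scan$flagged[match(truth_qtl$snp_id, scan$snp_id)]
message(sum(hit, na.rm = TRUE), " of ", nrow(truth_qtl),
        " planted QTL flagged by the comparator scan")

classes <- factor(adj$tolerance_class,
                  levels = c("tolerant", "moderate", "susceptible"))
best_rf <- readLines("results/stepwise/best_subset_random_forest.txt")
cm <- evaluate_subset(X, classes, best_rf,
                      model_spec("random_forest", seed = 1))$confusion
print(cm)

vips <- structure(vips_tab[c("snp_id", "vip", "chrom", "pos")],
                  class = c("vip_table", "data.frame"))
traces <- list(
  random_forest = read.csv("results/stepwise/trace_random_forest.csv",
                           stringsAsFactors = FALSE),
  svm_radial = read.csv("results/stepwise/trace_svm_radial.csv",
                        stringsAsFactors = FALSE))
curves <- list(
  random_forest = read.csv("results/stepwise/overfitting_curve_random_forest.csv"),
  svm_radial = read.csv("results/stepwise/overfitting_curve_svm_radial.csv"))

files <- render_reports("results/report",
                        vips = vips,
                        thresholded = vips_tab$snp_id[vips_tab$kept_after_threshold],
                        pruned = vips_tab$snp_id[vips_tab$kept_after_pruning],
                        trace = traces, curve = curves, scan = scan, cm = cm)
message("report bundle: ", length(files), " files under results/report/")
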