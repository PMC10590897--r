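#!/usr/bin/env Rscript
# Stage 1: simulate the study-scale panel.
#
# Emulates a multi-environment off-target dicamba trial: 551 inbred advanced
# breeding lines genotyped at 4,970 LD-blocked SNPs across 20 chromosomes
# (all MAF >= 0.05), with 2 large- and 8 small-effect planted QTL on the
# liability scale, rated on the 1-4 / 0.5-increment visual damage scale in
# 9 environments x 3 replicates. Raw matrices go to scratch/ (they are bulky
# and fully regenerable from the seed); small summaries and the simulation
# truth go to results/.

suppressMessages(library(mlgwas))

seed <- 20260926L
raw_dir <- "scratch/sim"
out_dir <- "results/sim"
dir.create(raw_dir, recursive = TRUE, showWarnings = FALSE)
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

message("simulating 551 lines x 4,970 SNPs ...")
sim <- simulate_genotypes(551, 4970, n_chromosomes = 20, block_size = 10,
                          within_block_corr = 0.9,
                          n_qtl_large = 2, n_qtl_small = 8,
                          effect_large = 0.6, effect_small = 0.15,
                          seed = seed)
ratings <- simulate_phenotypes(sim, n_envs = 9, n_reps = 3)

write_dosage_csv(sim$genotypes, file.path(raw_dir, "dosages.csv"))
write_snp_meta(sim$genotypes, file.path(raw_dir, "snp_meta.tsv"))
write_ratings_csv(ratings, file.path(raw_dir, "ratings.csv"))
write_truth(sim$truth, file.path(out_dir, "simulation_truth.yaml"))

qtl <- data.frame(snp_id = sim$truth$qtl_snp_ids,
                  effect = sim$truth$qtl_effects,
                  maf = sim$genotypes$maf[sim$truth$qtl_snp_ids])
write.csv(qtl, file.path(out_dir, "planted_qtl.csv"), row.names = FALSE)

message(sprintf("panel: %d lines x %d SNPs; MAF in [%.3f, %.3f]",
                nrow(sim$genotypes$dosages), ncol(sim$genotypes$dosages),
                min(sim$genotypes$maf), max(sim$genotypes$maf)))
message(sprintf("%d plot ratings; score distribution:", nrow(ratings)))
print(table(ratings$score))
message("planted QTL:")
print(qtl)
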