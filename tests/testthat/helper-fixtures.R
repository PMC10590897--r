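# Shared simulated datasets for the heavier recovery/overfitting checks:
# 300 lines x 1,000 SNPs with one planted large-effect QTL at an
# intermediate MAF, so the QTL explains well over 30% of the liability
# variance; 3 environments x 3 replicates of ordinal ratings, adjusted to
# genotype means by the REML model. Built once per test run and memoised.
.sim_cache <- new.env(parent = emptyenv())

planted_qtl_dataset <- function(seed) {
  key <- paste0("s", seed)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  sim <- simulate_genotypes(300, 1000, block_size = 10, within_block_corr = 0.6,
                            n_qtl_large = 1, n_qtl_small = 0,
                            effect_large = 1.2,
                            variance_components = c(genotype = 0.1, environment = 0.25,
                                                    gxe = 0.1, replicate = 0.05,
                                                    residual = 0.5),
                            seed = seed)
  ratings <- simulate_phenotypes(sim, n_envs = 3, n_reps = 3)
  adj <- suppressMessages(fit_adjusted_means(ratings))
  adj <- adj[match(rownames(sim$genotypes$dosages), adj$genotype_id), ]
  X <- impute_mean(sim$genotypes)
  fit <- fit_pls(X, adj$adjusted_score, max_components = 10, cv_folds = 10,
                 seed = seed)
  vips <- compute_vip(fit, sim$genotypes$snp_meta)
  out <- list(sim = sim, ratings = ratings, adj = adj, X = X, fit = fit,
              vips = vips)
  .sim_cache[[key]] <- out
  out
}

# A tiny deterministic three-class dataset where class is a noisy function
# of a handful of informative dosage columns.
toy_classification <- function(n = 150, p = 12, n_informative = 3, seed = 1,
                               noise_sd = 0.4) {
  set.seed(seed)
  X <- matrix(sample(0:2, n * p, replace = TRUE), n, p,
              dimnames = list(paste0("l", seq_len(n)), paste0("s", seq_len(p))))
  eff <- seq(1, 0.5, length.out = n_informative)
  lin <- drop(X[, seq_len(n_informative), drop = FALSE] %*% eff) +
    rnorm(n, sd = noise_sd)
  cls <- cut(lin, breaks = stats::quantile(lin, c(0, 1/3, 2/3, 1)),
             labels = c("tolerant", "moderate", "susceptible"),
             include.lowest = TRUE)
  list(X = X, classes = factor(as.character(cls),
                               levels = c("tolerant", "moderate", "susceptible")))
}
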