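#' Pipeline configuration
#'
#' Collects every tunable of the feature-selection workflow with the study
#' defaults: MAF filter 0.05, VIP cutoff 2.0, correlation cutoff 0.7,
#' 10-fold CV for PLS component selection, 5-fold CV for classification,
#' radial-SVM cost grid \{0.01, 0.1, 1, 10, 100, 1000\} and gamma grid
#' \{0.0001, 0.001, 0.01, 0.5, 1\}, and the floor(sqrt(p)) features-per-split
#' rule for the random forest.
#'
#' @param maf_threshold minor-allele-frequency filter.
#' @param vip_cutoff VIP selection threshold.
#' @param corr_cutoff pairwise |r| pruning threshold.
#' @param pls_folds,clf_folds CV folds for PLS and for the classifiers.
#' @param pls_max_components cap on PLS components considered.
#' @param rf_trees,svm_cost_grid,svm_gamma_grid classifier settings (see
#'   [model_spec()]).
#' @param max_iters forward-selection trace length cap (NULL = all
#'   candidates).
#' @param models which classifier families to run.
#' @param mode forward-selection semantics, "greedy" or "vip-order".
#' @param seed master seed for all stochastic stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(maf_threshold = 0.05, vip_cutoff = 2.0,
                            corr_cutoff = 0.7, pls_folds = 10L,
                            clf_folds = 5L, pls_max_components = 10L,
                            rf_trees = 500L,
                            svm_cost_grid = c(0.01, 0.1, 1, 10, 100, 1000),
                            svm_gamma_grid = c(0.0001, 0.001, 0.01, 0.5, 1),
                            max_iters = NULL,
                            models = c("random_forest", "svm_radial"),
                            mode = c("greedy", "vip-order"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(maf_threshold >= 0, maf_threshold <= 0.5, vip_cutoff >= 0,
            corr_cutoff > 0, corr_cutoff <= 1)
  models <- match.arg(models, several.ok = TRUE)
  structure(list(maf_threshold = maf_threshold, vip_cutoff = vip_cutoff,
                 corr_cutoff = corr_cutoff, pls_folds = as.integer(pls_folds),
                 clf_folds = as.integer(clf_folds),
                 pls_max_components = as.integer(pls_max_components),
                 rf_trees = as.integer(rf_trees),
                 svm_cost_grid = svm_cost_grid, svm_gamma_grid = svm_gamma_grid,
                 max_iters = max_iters, models = models, mode = mode,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full feature-selection pipeline
#'
#' Stages, in order: (1) adjust plot ratings to per-genotype means and
#' tolerance classes; (2) MAF filter and mean imputation; (3) PLS fit and
#' VIP scores; (4) VIP threshold; (5) correlation pruning; (6) forward
#' stepwise selection under each requested classifier family; (7) report
#' bundle plus a machine-readable run manifest recording configuration,
#' seeds, versions and per-stage counts — so the SNP funnel (all SNPs ->
#' VIP-selected -> pruned -> best subset) is auditable on any dataset.
#'
#' @param genotypes a [genotype_matrix()] (or path readable by
#'   [read_genotypes()]).
#' @param ratings plot-level ratings data.frame (or CSV path with columns
#'   genotype_id, environment_id, replicate_id, score).
#' @param out_dir output directory for reports and the manifest.
#' @param config a [pipeline_config()].
#' @return invisible list with elements adjusted, genotypes, fit, vips,
#'   thresholded, pruned, traces, best_subsets, scan, manifest.
#' @export
run_pipeline <- function(genotypes, ratings, out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(genotypes)) genotypes <- read_genotypes(genotypes)
  if (is.character(ratings)) ratings <- utils::read.csv(ratings, stringsAsFactors = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  counts <- list(n_lines = nrow(genotypes$dosages), n_snps_input = ncol(genotypes$dosages))

  # 1. phenotype adjustment
  adj <- fit_adjusted_means(ratings)
  adj_attrs <- attributes(adj)[c("varcomp", "boundary", "method")]
  adj <- adj[adj$genotype_id %in% rownames(genotypes$dosages), , drop = FALSE]
  attributes(adj) <- c(attributes(adj), adj_attrs)
  geno <- genotypes
  geno$dosages <- geno$dosages[adj$genotype_id, , drop = FALSE]
  counts$n_genotypes_adjusted <- nrow(adj)

  # 2. genotype QC
  geno <- genotype_matrix(geno$dosages, geno$snp_meta)
  geno <- filter_maf(geno, config$maf_threshold)
  counts$n_snps_after_maf <- ncol(geno$dosages)
  X <- impute_mean(geno)

  # 3. PLS + VIP
  fit <- fit_pls(X, adj$adjusted_score,
                 max_components = min(config$pls_max_components,
                                      nrow(X) - 1L, ncol(X)),
                 cv_folds = config$pls_folds, seed = config$seed)
  vips <- compute_vip(fit, geno$snp_meta)

  # 4.-5. threshold and prune
  thresholded <- threshold_vip(vips, config$vip_cutoff)
  counts$n_snps_after_vip <- length(thresholded)
  pruned <- if (length(thresholded))
    prune_correlated(X, vips, config$corr_cutoff, snp_subset = thresholded)
  else character(0)
  counts$n_snps_after_pruning <- length(pruned)

  # 6. forward stepwise per model family
  traces <- list()
  best_subsets <- list()
  if (length(pruned) == 0) {
    warning("empty selection after VIP threshold ", config$vip_cutoff,
            "; stepwise stage skipped", call. = FALSE)
  } else {
    for (fam in config$models) {
      spec <- model_spec(fam, rf_trees = config$rf_trees,
                         svm_cost_grid = config$svm_cost_grid,
                         svm_gamma_grid = config$svm_gamma_grid,
                         cv_folds = config$clf_folds, seed = config$seed)
      tr <- forward_select(X, adj$tolerance_class, pruned, spec,
                           max_iters = config$max_iters %||% length(pruned),
                           mode = config$mode)
      traces[[fam]] <- tr
      best_subsets[[fam]] <- attr(tr, "best_subset")
      counts[[paste0("best_subset_", fam)]] <- length(attr(tr, "best_subset"))
    }
  }

  # 7. comparator scan + reports + manifest
  scan <- single_marker_scan(geno, adj$adjusted_score)
  cm <- NULL
  if (length(traces)) {
    fam1 <- names(traces)[1]
    spec1 <- model_spec(fam1, rf_trees = config$rf_trees,
                        svm_cost_grid = config$svm_cost_grid,
                        svm_gamma_grid = config$svm_gamma_grid,
                        cv_folds = config$clf_folds, seed = config$seed)
    cm <- evaluate_subset(X, adj$tolerance_class, best_subsets[[fam1]], spec1)$confusion
  }
  render_reports(out_dir, vips = vips, thresholded = thresholded,
                 pruned = pruned, trace = traces, scan = scan, cm = cm)
  write_adjusted(adj, file.path(out_dir, "adjusted_phenotypes.csv"),
                 file.path(out_dir, "variance_components.txt"))

  manifest <- list(package_version = as.character(utils::packageVersion("mlgwas")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   config = unclass(config), stages = counts,
                   stage_order = c("adjust", "maf_filter", "pls_vip",
                                   "vip_threshold", "prune", "forward_select",
                                   "report"),
                   best_subsets = best_subsets)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(adjusted = adj, genotypes = geno, fit = fit, vips = vips,
                 thresholded = thresholded, pruned = pruned, traces = traces,
                 best_subsets = best_subsets, scan = scan, manifest = manifest))
}

#' Write a simulation-truth sidecar
#' @param truth a [simulation_truth()].
#' @param path YAML output path.
#' @export
write_truth <- function(truth, path) {
  yaml::write_yaml(lapply(unclass(truth), function(x)
    if (is.numeric(x)) as.numeric(x) else x), path)
  invisible(path)
}

#' Write plot ratings as long-format CSV
#' @param ratings data.frame from [simulate_phenotypes()].
#' @param path output CSV.
#' @export
write_ratings_csv <- function(ratings, path) {
  utils::write.csv(ratings, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
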