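#!/usr/bin/env Rscript
# Stage 4: forward stepwise selection under RF and radial SVM, plus the
# overfitting curve.
#
# Starting from the top 40 pruned VIP-selected SNPs, each classifier family
# runs the greedy forward loop (5-fold stratified CV, pooled confusion
# metrics per iteration; the trace continues past the first non-improvement
# so the overfitting behaviour stays visible) out to a 40-iteration trace.
# The overfitting curve re-evaluates VIP-ranked prefixes from 1 SNP up to
# 2,000 SNPs.
#
# This is by far the slowest stage (hours of single-core SVM tuning at the
# full panel size), so progress is checkpointed under scratch/ at the
# granularity of single candidate evaluations: re-running the script
# resumes where it stopped, and it exits cleanly once its per-invocation
# time budget is spent. The greedy semantics are exactly those of
# forward_select() (argmax of overall accuracy, ties to the higher-VIP
# candidate), built on the same evaluate_subset() calls.

suppressMessages(library(mlgwas))

budget_s <- as.numeric(Sys.getenv("STEPWISE_BUDGET_S", "520"))
t_start <- Sys.time()
elapsed <- function() as.numeric(difftime(Sys.time(), t_start, units = "secs"))

geno <- read_genotypes("scratch/sim/dosages.csv", "dosage",
                       meta_path = "scratch/sim/snp_meta.tsv")
adj <- read.csv("results/adjust/adjusted_phenotypes.csv", stringsAsFactors = FALSE)
adj <- adj[match(rownames(geno$dosages), adj$genotype_id), ]
vips <- read.csv("results/select/vip_table.csv", stringsAsFactors = FALSE)
pruned <- readLines("results/select/selected_snps.txt")
out_dir <- "results/stepwise"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

X <- impute_mean(geno)
classes <- factor(adj$tolerance_class,
                  levels = c("tolerant", "moderate", "susceptible"))
ranked_all <- vips$snp_id[order(-vips$vip)]
cand <- head(pruned, 40)
max_iters <- length(cand)

run_family <- function(fam) {
  trace_f <- file.path(out_dir, paste0("trace_", fam, ".csv"))
  if (file.exists(trace_f)) return(TRUE)
  state_f <- file.path("scratch", paste0("stepwise_", fam, ".rds"))
  st <- if (file.exists(state_f)) readRDS(state_f)
        else list(chosen = character(0), rows = list(), accs = numeric(0))
  spec <- model_spec(fam, seed = 1)
  repeat {
    k <- length(st$chosen) + 1L
    if (k > max_iters) break
    remaining <- setdiff(cand, st$chosen)
    for (s in setdiff(remaining, names(st$accs))) {
      if (elapsed() > budget_s) {
        saveRDS(st, state_f)
        message(fam, ": budget spent at iteration ", k, " (",
                length(st$accs), "/", length(remaining),
                " candidates scored); re-run to resume")
        return(FALSE)
      }
      ev <- evaluate_subset(X, classes, c(st$chosen, s), spec)
      st$accs[s] <- ev$overall_accuracy
      saveRDS(st, state_f)
    }
    accs <- st$accs[remaining]          # candidate order = descending VIP
    pick <- remaining[which.max(accs)]  # ties -> higher VIP
    ev <- evaluate_subset(X, classes, c(st$chosen, pick), spec)
    st$rows[[k]] <- mlgwas:::trace_row(k, pick, c(st$chosen, pick), ev)
    st$chosen <- c(st$chosen, pick)
    st$accs <- numeric(0)
    saveRDS(st, state_f)
    message(sprintf("  %s iteration %d: +%s, accuracy %.3f", fam, k, pick,
                    ev$overall_accuracy))
  }
  trace <- do.call(rbind, st$rows)
  write.csv(trace, trace_f, row.names = FALSE)
  b <- which.max(trace$overall_accuracy)
  writeLines(strsplit(trace$snps[b], ";")[[1]],
             file.path(out_dir, paste0("best_subset_", fam, ".txt")))
  message(sprintf(
    "%s: best %d SNPs, accuracy %.2f; 1 SNP %.2f; all %d candidates %.2f",
    fam, b, trace$overall_accuracy[b], trace$overall_accuracy[1],
    nrow(trace), trace$overall_accuracy[nrow(trace)]))
  TRUE
}

run_curve <- function(fam) {
  grid <- c(1, 2, 5, 10, 20, length(pruned), 100, 250, 500, 1000, 2000)
  grid <- unique(pmin(grid, length(ranked_all)))
  curve_f <- file.path(out_dir, paste0("overfitting_curve_", fam, ".csv"))
  done <- if (file.exists(curve_f)) read.csv(curve_f)$subset_size else integer(0)
  spec <- model_spec(fam, seed = 1)
  for (s in setdiff(grid, done)) {
    if (elapsed() > budget_s) {
      message(fam, " curve: budget spent; re-run to resume")
      return(FALSE)
    }
    cv <- overfitting_curve(X, classes, ranked_all, spec, s)
    prev <- if (file.exists(curve_f)) read.csv(curve_f) else NULL
    write.csv(rbind(prev, cv), curve_f, row.names = FALSE)
    message(sprintf("  %s curve: %d SNPs -> accuracy %.3f", fam, s,
                    cv$overall_accuracy))
  }
  TRUE
}

done <- TRUE
for (fam in c("random_forest", "svm_radial")) done <- done && run_family(fam)
if (done) for (fam in c("random_forest", "svm_radial")) done <- done && run_curve(fam)

if (done) {
  rf <- readLines(file.path(out_dir, "best_subset_random_forest.txt"))
  sv <- readLines(file.path(out_dir, "best_subset_svm_radial.txt"))
  message(length(intersect(rf, sv)), " SNPs shared by the RF and SVM best subsets: ",
          paste(intersect(rf, sv), collapse = ", "))
  message("stage 4 complete")
} else message("stage 4 incomplete; re-run analysis/04_stepwise.R to resume")
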