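#' Classifier configuration for the stepwise selection loop
#'
#' @param family "random_forest" (features-per-split = floor(sqrt(p))) or
#'   "svm_radial" (radial kernel, cost/gamma tuned by nested grid search).
#' @param rf_trees trees per forest (default 500).
#' @param rf_mtry features per split; NULL = floor(sqrt(p)).
#' @param svm_cost_grid,svm_gamma_grid hyperparameter grids for the radial
#'   SVM, searched on the training folds only.
#' @param cv_folds outer stratified cross-validation folds (default 5).
#' @param tune_folds inner folds for the SVM grid search (default 3).
#' @param seed integer; fixes fold assignment and the tree-level RNG, making
#'   repeat evaluations identical on a given platform.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = c("random_forest", "svm_radial"),
                       rf_trees = 500L, rf_mtry = NULL,
                       svm_cost_grid = c(0.01, 0.1, 1, 10, 100, 1000),
                       svm_gamma_grid = c(0.0001, 0.001, 0.01, 0.5, 1),
                       cv_folds = 5L, tune_folds = 3L, seed = 1L) {
  family <- match.arg(family)
  stopifnot(cv_folds >= 2, tune_folds >= 2, rf_trees >= 1,
            length(svm_cost_grid) >= 1, length(svm_gamma_grid) >= 1)
  structure(list(family = family, rf_trees = as.integer(rf_trees),
                 rf_mtry = rf_mtry, svm_cost_grid = svm_cost_grid,
                 svm_gamma_grid = svm_gamma_grid,
                 cv_folds = as.integer(cv_folds),
                 tune_folds = as.integer(tune_folds),
                 seed = as.integer(seed)),
            class = "model_spec")
}

# Train on (Xtr, ytr), predict labels for Xte. SVM hyperparameters are tuned
# by an inner stratified grid search that never sees Xte.
fit_predict <- function(Xtr, ytr, Xte, spec) {
  ytr <- droplevels(factor(ytr, levels = TOLERANCE_LEVELS))
  if (nlevels(ytr) < 2) stop("training fold has a single class")
  if (spec$family == "random_forest") {
    mtry <- spec$rf_mtry %||% max(1L, floor(sqrt(ncol(Xtr))))
    fit <- randomForest::randomForest(x = Xtr, y = ytr, ntree = spec$rf_trees,
                                      mtry = min(mtry, ncol(Xtr)))
    as.character(stats::predict(fit, Xte))
  } else {
    grid <- expand.grid(gamma = spec$svm_gamma_grid, cost = spec$svm_cost_grid)
    inner <- make_stratified_folds(ytr, spec$tune_folds)
    k_in <- attr(inner, "k")
    acc <- numeric(nrow(grid))
    for (i in seq_len(nrow(grid))) {
      correct <- 0L
      for (f in seq_len(k_in)) {
        tr <- inner != f
        ytr_in <- droplevels(ytr[tr])
        if (nlevels(ytr_in) < 2) next
        m <- e1071::svm(x = Xtr[tr, , drop = FALSE], y = ytr_in,
                        kernel = "radial", cost = grid$cost[i],
                        gamma = grid$gamma[i])
        correct <- correct + sum(as.character(stats::predict(
          m, Xtr[!tr, , drop = FALSE])) == as.character(ytr[!tr]))
      }
      acc[i] <- correct
    }
    best <- which.max(acc)  # ties: first combo in grid order
    fit <- e1071::svm(x = Xtr, y = ytr, kernel = "radial",
                      cost = grid$cost[best], gamma = grid$gamma[best])
    as.character(stats::predict(fit, Xte))
  }
}

#' Cross-validated metrics for one SNP subset
#'
#' Stratified k-fold cross-validation with fold assignment fixed by the
#' spec's seed; out-of-fold predictions are pooled into a single confusion
#' matrix from which the overall and per-class metrics are computed. A class
#' rarer than the fold count reduces the fold count with a warning; a class
#' absent from some training fold is refit on the remaining classes with a
#' warning.
#'
#' @param X dosage matrix (lines x SNPs), numeric, no missing values.
#' @param classes tolerance labels, one per line.
#' @param snp_set non-empty character vector of columns of X to use.
#' @param spec a [model_spec()].
#' @return list with `confusion` ([confusion()]), `overall_accuracy`
#'   (proportion in [0, 1]), `class_metrics` (data.frame, one row per class)
#'   and `n_folds`.
#' @export
evaluate_subset <- function(X, classes, snp_set, spec) {
  stopifnot(length(snp_set) >= 1, inherits(spec, "model_spec"))
  X <- as.matrix(X)
  if (!all(snp_set %in% colnames(X))) stop("snp_set not all present in X")
  classes <- factor(as.character(classes), levels = TOLERANCE_LEVELS)
  classes <- droplevels(classes)
  if (nlevels(classes) < 2) stop("need >= 2 classes present")
  Xs <- X[, snp_set, drop = FALSE]

  set.seed(spec$seed)
  fold <- make_stratified_folds(classes, spec$cv_folds)
  k <- attr(fold, "k")
  pred <- character(length(classes))
  for (f in seq_len(k)) {
    te <- fold == f
    ytr <- classes[!te]
    if (nlevels(droplevels(ytr)) < nlevels(classes))
      warning("a class is absent from training fold ", f,
              "; refitting on remaining classes", call. = FALSE)
    pred[te] <- fit_predict(Xs[!te, , drop = FALSE], ytr,
                            Xs[te, , drop = FALSE], spec)
  }
  cm <- confusion(classes, pred, levels = levels(classes))
  list(confusion = cm,
       overall_accuracy = overall_accuracy(cm) / 100,
       class_metrics = all_class_metrics(cm),
       n_folds = k)
}

# One trace row: iteration, snp added, cumulative set, overall + per-class.
trace_row <- function(iter, snp, snps, ev) {
  m <- ev$class_metrics
  row <- data.frame(iteration = iter, n_snps = length(snps), snp_added = snp,
                    snps = paste(snps, collapse = ";"),
                    overall_accuracy = ev$overall_accuracy,
                    stringsAsFactors = FALSE)
  for (cl in m$class) {
    mm <- m[m$class == cl, ]
    row[[paste0(cl, "_accuracy")]] <- mm$accuracy
    row[[paste0(cl, "_precision")]] <- mm$precision
    row[[paste0(cl, "_specificity")]] <- mm$specificity
  }
  row
}

#' Forward stepwise SNP selection under cross-validated classification
#'
#' Iteration 1 fits the highest-VIP candidate alone. In greedy mode (the
#' default), iteration k+1 evaluates every remaining candidate as the
#' (k+1)-th predictor and retains the one maximizing overall accuracy; ties
#' go to the candidate earlier in the (descending-VIP, then genome-order)
#' candidate ranking. In "vip-order" mode candidates are added in their
#' given order without competition. The trace deliberately continues past
#' the first non-improvement up to `max_iters`, so the overfitting behaviour
#' of later additions stays observable; `best_subset` is the argmax of
#' overall accuracy over the whole trace (earliest iteration on ties).
#'
#' @param X dosage matrix.
#' @param classes tolerance labels.
#' @param candidates SNP ids ranked by descending VIP (e.g. the
#'   [prune_correlated()] output).
#' @param spec a [model_spec()].
#' @param max_iters trace length (<= number of candidates).
#' @param patience consecutive non-improvements tolerated before the loop is
#'   considered concluded for reporting purposes (`stop_iteration`); the
#'   trace itself always runs to `max_iters`.
#' @param mode "greedy" or "vip-order".
#' @return object of class `step_trace`: data.frame with one row per
#'   iteration and attributes `best_iteration`, `best_subset`,
#'   `stop_iteration`, `mode`.
#' @export
forward_select <- function(X, classes, candidates, spec,
                           max_iters = length(candidates), patience = 0L,
                           mode = c("greedy", "vip-order")) {
  mode <- match.arg(mode)
  if (length(candidates) == 0) stop("empty candidate set")
  max_iters <- min(max_iters, length(candidates))
  X <- as.matrix(X)

  current <- character(0)
  remaining <- candidates
  rows <- vector("list", max_iters)
  for (k in seq_len(max_iters)) {
    if (mode == "vip-order") {
      add <- remaining[1]
      ev <- evaluate_subset(X, classes, c(current, add), spec)
    } else {
      accs <- vapply(remaining, function(s)
        evaluate_subset(X, classes, c(current, s), spec)$overall_accuracy,
        numeric(1))
      add <- remaining[which.max(accs)]  # ties: earliest in candidate ranking
      ev <- evaluate_subset(X, classes, c(current, add), spec)
    }
    current <- c(current, add)
    remaining <- setdiff(remaining, add)
    rows[[k]] <- trace_row(k, add, current, ev)
  }
  trace <- do.call(rbind, rows)
  best <- which.max(trace$overall_accuracy)  # earliest on ties
  # reporting stop point: first iteration followed by > patience
  # consecutive non-improvements of the running maximum
  stop_iter <- nrow(trace)
  no_gain <- 0L
  for (k in seq_len(nrow(trace))[-1]) {
    no_gain <- if (trace$overall_accuracy[k] > max(trace$overall_accuracy[1:(k - 1)]))
      0L else no_gain + 1L
    if (no_gain > patience) { stop_iter <- k - no_gain; break }
  }
  structure(trace,
            best_iteration = best,
            best_subset = strsplit(trace$snps[best], ";")[[1]],
            stop_iteration = stop_iter,
            mode = mode,
            class = c("step_trace", "data.frame"))
}

#' Accuracy as a function of VIP-ranked subset size
#'
#' For each size s in `grid`, runs [evaluate_subset()] on the top-s SNPs of
#' the VIP ranking. On data where few planted or real loci carry the signal,
#' accuracy peaks at small s and declines as noise predictors are added —
#' the overfitting curve.
#'
#' @param X dosage matrix.
#' @param classes tolerance labels.
#' @param ranked_snps SNP ids in descending VIP order.
#' @param spec a [model_spec()].
#' @param grid subset sizes (each <= length(ranked_snps)).
#' @return data.frame(subset_size, overall_accuracy).
#' @export
overfitting_curve <- function(X, classes, ranked_snps, spec, grid) {
  stopifnot(all(grid >= 1), all(grid <= length(ranked_snps)))
  acc <- vapply(grid, function(s)
    evaluate_subset(X, classes, ranked_snps[seq_len(s)], spec)$overall_accuracy,
    numeric(1))
  data.frame(subset_size = as.integer(grid), overall_accuracy = acc)
}
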