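spec_rf <- function(seed = 1, trees = 150) model_spec("random_forest",
                                                      rf_trees = trees, seed = seed)

test_that("a perfectly separating SNP yields accuracy 1 in both families", {
  set.seed(1)
  dos <- sample(0:2, 120, replace = TRUE)
  X <- cbind(causal = dos, noise = sample(0:2, 120, replace = TRUE))
  rownames(X) <- paste0("l", 1:120)
  classes <- c("tolerant", "moderate", "susceptible")[dos + 1]
  for (fam in c("random_forest", "svm_radial")) {
    spec <- model_spec(fam, rf_trees = 100, seed = 2)
    ev <- evaluate_subset(X, classes, "causal", spec)
    expect_equal(ev$overall_accuracy, 1.0)
  }
})

test_that("repeat evaluation under one seed gives the identical pooled confusion", {
  toy <- toy_classification(seed = 3)
  spec <- spec_rf(seed = 7)
  e1 <- evaluate_subset(toy$X, toy$classes, c("s1", "s2"), spec)
  e2 <- evaluate_subset(toy$X, toy$classes, c("s1", "s2"), spec)
  expect_identical(e1$confusion$table, e2$confusion$table)
})

test_that("stratified folds partition the lines and respect rare classes", {
  set.seed(4)
  classes <- factor(rep(c("tolerant", "moderate", "susceptible"), c(6, 40, 14)))
  fold <- mlgwas:::make_stratified_folds(classes, 5)
  expect_equal(length(fold), 60)
  expect_true(all(table(fold) > 0))
  # every class present in every fold
  expect_true(all(table(classes, fold) > 0))
  # a class rarer than k reduces the fold count with a warning
  rare <- factor(rep(c("tolerant", "moderate"), c(3, 30)))
  expect_warning(f2 <- mlgwas:::make_stratified_folds(rare, 5), "reducing")
  expect_equal(attr(f2, "k"), 3L)
})

test_that("single-candidate forward selection returns a one-row trace", {
  toy <- toy_classification(seed = 5)
  tr <- forward_select(toy$X, toy$classes, "s1", spec_rf(seed = 5))
  expect_equal(nrow(tr), 1)
  expect_equal(attr(tr, "best_subset"), "s1")
  expect_error(forward_select(toy$X, toy$classes, character(0), spec_rf()),
               "empty candidate")
})

test_that("a noise SNP cannot displace a perfect predictor from the best subset", {
  set.seed(6)
  dos <- sample(0:2, 150, replace = TRUE)
  X <- cbind(perfect = dos, noise = sample(0:2, 150, replace = TRUE))
  rownames(X) <- paste0("l", 1:150)
  classes <- c("tolerant", "moderate", "susceptible")[dos + 1]
  tr <- forward_select(X, classes, c("perfect", "noise"), spec_rf(seed = 6),
                       max_iters = 2)
  expect_equal(tr$snp_added[1], "perfect")
  expect_equal(tr$overall_accuracy[1], 1.0)
  expect_equal(attr(tr, "best_subset"), "perfect")
})

test_that("the greedy trace equals a step-by-step brute-force recomputation", {
  toy <- toy_classification(n = 100, p = 6, seed = 8)
  cand <- paste0("s", 1:4)
  spec <- spec_rf(seed = 9, trees = 100)
  tr <- forward_select(toy$X, toy$classes, cand, spec, max_iters = 4)
  # independently coded greedy loop over evaluate_subset
  chosen <- character(0)
  left <- cand
  for (k in 1:4) {
    accs <- sapply(left, function(s)
      evaluate_subset(toy$X, toy$classes, c(chosen, s), spec)$overall_accuracy)
    pick <- left[which.max(accs)]
    expect_equal(tr$snp_added[k], pick)
    expect_equal(tr$overall_accuracy[k], unname(max(accs)))
    chosen <- c(chosen, pick)
    left <- setdiff(left, pick)
  }
})

test_that("greedy additions are stepwise-optimal; first pick dominates any fixed order", {
  toy <- toy_classification(n = 120, p = 8, seed = 10)
  cand <- paste0("s", c(4, 1, 6, 2, 5))  # deliberately unhelpful fixed order
  spec <- spec_rf(seed = 11, trees = 100)
  greedy <- forward_select(toy$X, toy$classes, cand, spec, max_iters = 4)
  fixed <- forward_select(toy$X, toy$classes, cand, spec, max_iters = 4,
                          mode = "vip-order")
  expect_equal(fixed$snp_added, cand[1:4])
  # iteration 1 of greedy evaluates every candidate alone, so it can only
  # match or beat any fixed order's opener
  expect_gte(greedy$overall_accuracy[1], fixed$overall_accuracy[1] - 1e-12)
  # each greedy addition maximizes accuracy over the remaining candidates,
  # conditional on its own prefix
  chosen <- character(0)
  for (k in seq_len(4)) {
    left <- setdiff(cand, chosen)
    accs <- vapply(left, function(s)
      evaluate_subset(toy$X, toy$classes, c(chosen, s), spec)$overall_accuracy,
      numeric(1))
    expect_equal(greedy$overall_accuracy[k], unname(max(accs)))
    chosen <- c(chosen, greedy$snp_added[k])
  }
})

test_that("best-subset metrics reproduce under re-evaluation with the same seed", {
  toy <- toy_classification(seed = 12)
  spec <- spec_rf(seed = 13)
  tr <- forward_select(toy$X, toy$classes, paste0("s", 1:4), spec, max_iters = 3)
  best <- attr(tr, "best_subset")
  ev <- evaluate_subset(toy$X, toy$classes, best, spec)
  expect_equal(tr$overall_accuracy[attr(tr, "best_iteration")],
               ev$overall_accuracy)
})

test_that("the overfitting curve is consistent with evaluate_subset and deterministic", {
  toy <- toy_classification(seed = 14)
  spec <- spec_rf(seed = 15)
  ranked <- paste0("s", 1:8)
  cv <- overfitting_curve(toy$X, toy$classes, ranked, spec, grid = c(1, 1, 4))
  ev1 <- evaluate_subset(toy$X, toy$classes, ranked[1], spec)
  expect_equal(cv$overall_accuracy[1], ev1$overall_accuracy)
  expect_equal(cv$overall_accuracy[1], cv$overall_accuracy[2])
})

test_that("test rows are scored independently: no test-set information leaks", {
  # with the RNG pinned, predicting the whole held-out fold at once must
  # equal predicting each held-out line alone — the trained model (including
  # the nested SVM grid search) can only have seen the training rows
  toy <- toy_classification(n = 90, p = 5, seed = 16)
  spec <- model_spec("svm_radial", svm_cost_grid = c(0.1, 1, 10),
                     svm_gamma_grid = c(0.01, 0.1), cv_folds = 3, seed = 17)
  tr_idx <- 1:60
  te_idx <- 61:90
  set.seed(spec$seed)
  p_all <- mlgwas:::fit_predict(toy$X[tr_idx, ], toy$classes[tr_idx],
                                toy$X[te_idx, ], spec)
  p_single <- vapply(te_idx, function(i) {
    set.seed(spec$seed)
    mlgwas:::fit_predict(toy$X[tr_idx, ], toy$classes[tr_idx],
                         toy$X[i, , drop = FALSE], spec)
  }, character(1))
  expect_identical(p_all, unname(p_single))
  # and the training data does matter: relabelling it changes predictions
  set.seed(spec$seed)
  p_scrambled <- mlgwas:::fit_predict(toy$X[tr_idx, ],
                                      sample(as.character(toy$classes[tr_idx])),
                                      toy$X[te_idx, ], spec)
  expect_false(identical(p_all, p_scrambled))
})
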