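test_that("a single noise-free causal SNP is explained by one component", {
  set.seed(1)
  X <- matrix(sample(0:2, 80 * 10, replace = TRUE), 80, 10,
              dimnames = list(NULL, paste0("s", 1:10)))
  # make the remaining columns exactly orthogonal to the causal one so the
  # problem is genuinely rank-1 in the response
  causal <- scale(X[, 4])
  X_orth <- apply(X[, -4], 2, function(col)
    stats::residuals(stats::lm(col ~ causal)))
  Xr <- cbind(s4 = X[, 4], X_orth)
  y <- 2 * X[, 4]
  fit <- fit_pls(Xr, y, max_components = 5, cv_folds = 5, seed = 1)
  expect_gt(fit$y_variance_explained[1], 0.999)
})

test_that("the CV error curve is deterministic given the seed", {
  set.seed(2)
  X <- matrix(rnorm(60 * 30), 60, 30, dimnames = list(NULL, paste0("s", 1:30)))
  y <- rnorm(60)
  f1 <- fit_pls(X, y, max_components = 5, cv_folds = 5, seed = 42)
  f2 <- fit_pls(X, y, max_components = 5, cv_folds = 5, seed = 42)
  expect_identical(f1$cv_error_curve, f2$cv_error_curve)
  expect_identical(f1$n_components, f2$n_components)
})

test_that("on pure noise the one-SE rule picks very few components", {
  small <- 0L
  for (s in 1:20) {
    set.seed(s)
    X <- matrix(rnorm(200 * 500), 200, 500,
                dimnames = list(NULL, paste0("s", 1:500)))
    y <- rnorm(200)
    fit <- fit_pls(X, y, max_components = 8, cv_folds = 10, seed = s)
    if (fit$n_components <= 2) small <- small + 1L
  }
  expect_gte(small, 18)
})

test_that("degenerate PLS inputs error", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_pls(X, rep(1, 20), max_components = 2), "constant response")
  expect_error(fit_pls(X, rnorm(20), max_components = 0), ">= 1")
  expect_error(fit_pls(X, rnorm(20), max_components = 10), "max_components")
})

test_that("two predictors with equal weight share VIP 1.0", {
  set.seed(3)
  z <- rnorm(100)
  X <- cbind(a = z + rnorm(100, sd = 1e-9), b = z + rnorm(100, sd = 1e-9))
  y <- z
  fit <- fit_pls(X, y, n_components = 1)
  v <- compute_vip(fit)
  expect_equal(v$vip, c(1, 1), tolerance = 1e-4)
})

test_that("VIP normalization and the independent formula oracle agree", {
  set.seed(4)
  X <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, paste0("s", 1:5)))
  y <- X[, 1] + 0.5 * X[, 2] + rnorm(50, sd = 0.5)
  fit <- fit_pls(X, y, n_components = 2)
  v <- compute_vip(fit)
  expect_equal(mean(v$vip^2), 1, tolerance = 1e-6)
  expect_equal(sum(v$vip^2), ncol(X), tolerance = 1e-6)
  expect_equal(v$vip, vip_direct(fit), tolerance = 1e-10)
})

test_that("VIP scores match the mixOmics reference implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(5)
  X <- matrix(rnorm(60 * 15), 60, 15, dimnames = list(NULL, paste0("s", 1:15)))
  y <- X[, 1] * 2 + X[, 2] + rnorm(60, sd = 0.5)
  fit <- fit_pls(X, y, n_components = 3)
  ref <- mixOmics::vip(mixOmics::pls(X, y, ncomp = 3, scale = TRUE,
                                     mode = "regression"))
  expect_equal(compute_vip(fit)$vip, unname(ref[, 3]), tolerance = 1e-8)
})

test_that("the VIP threshold keeps the boundary and orders by descending VIP", {
  v <- structure(data.frame(snp_id = c("A", "B", "C"),
                            vip = c(3.16, 1.99, 2.00), n_components = 2,
                            chrom = c(1, 1, 2), pos = c(10, 20, 5)),
                 class = c("vip_table", "data.frame"))
  expect_equal(threshold_vip(v, 2.0), c("A", "C"))
  expect_equal(threshold_vip(v, 0), c("A", "C", "B"))
  expect_warning(out <- threshold_vip(v, 99), "empty")
  expect_length(out, 0)
  # idempotence: thresholding the already-thresholded table is a no-op
  v2 <- v[v$snp_id %in% threshold_vip(v, 2.0), ]
  expect_equal(threshold_vip(v2, 2.0), threshold_vip(v, 2.0))
})

test_that("correlation pruning drops the lower-VIP member of a correlated pair", {
  set.seed(6)
  base <- rnorm(100)
  X <- cbind(A = base + rnorm(100, sd = 0.3),     # r(A,B) high
             B = base + rnorm(100, sd = 0.3),
             C = rnorm(100))
  v <- structure(data.frame(snp_id = c("A", "B", "C"), vip = c(3.0, 2.5, 2.1),
                            n_components = 1),
                 class = c("vip_table", "data.frame"))
  stopifnot(abs(cor(X[, "A"], X[, "B"])) >= 0.7,
            abs(cor(X[, "A"], X[, "C"])) < 0.7,
            abs(cor(X[, "B"], X[, "C"])) < 0.7)
  expect_equal(prune_correlated(X, v), c("A", "C"))
  # all pairwise |r| < cutoff: identity in VIP order
  expect_equal(prune_correlated(X[, c("A", "C")], v,
                                snp_subset = c("A", "C")), c("A", "C"))
  # zero-variance column dropped with a message
  X2 <- cbind(X, D = rep(1, 100))
  v2 <- rbind(v, data.frame(snp_id = "D", vip = 2.2, n_components = 1))
  expect_message(out <- prune_correlated(X2, v2), "zero-variance")
  expect_false("D" %in% out)
})

test_that("pruning is invariant to candidate input ordering", {
  set.seed(7)
  X <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("s", 1:8)))
  X[, 2] <- X[, 1] + rnorm(60, sd = 0.2)
  X[, 5] <- X[, 4] + rnorm(60, sd = 0.2)
  v <- structure(data.frame(snp_id = paste0("s", 1:8),
                            vip = c(3, 2.8, 2.6, 2.4, 2.2, 2.0, 1.8, 1.6),
                            n_components = 1),
                 class = c("vip_table", "data.frame"))
  a <- prune_correlated(X, v, snp_subset = paste0("s", 1:8))
  b <- prune_correlated(X, v, snp_subset = paste0("s", sample(1:8)))
  expect_equal(a, b)
})

test_that("greedy pruning lands on a rule-consistent terminal state", {
  # exhaustive-enumeration oracle over random 8-SNP instances
  for (s in 1:10) {
    set.seed(s)
    n <- 40
    p <- 8
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("s", 1:p)))
    # inject correlation structure
    for (j in sample(2:p, 3)) X[, j] <- X[, j - 1] + rnorm(n, sd = 0.5)
    vip <- setNames(round(runif(p, 1, 4), 3), colnames(X))
    v <- structure(data.frame(snp_id = names(vip), vip = as.numeric(vip),
                              n_components = 1),
                   class = c("vip_table", "data.frame"))
    kept <- prune_correlated(X, v, snp_subset = colnames(X))
    R <- cor(X)
    # kept set has no violating pair
    if (length(kept) > 1)
      expect_lt(max(abs(R[kept, kept][upper.tri(R[kept, kept])])), 0.7)
    # every dropped SNP is the lower-VIP member of a pair with a kept SNP
    for (d in setdiff(colnames(X), kept)) {
      partners <- kept[abs(R[d, kept]) >= 0.7]
      expect_true(length(partners) > 0)
      expect_true(all(vip[partners[which.max(vip[partners])]] >= vip[d]))
    }
    # and the greedy outcome is reachable under the pairwise drop rule
    terminals <- prune_terminal_states(R, vip, 0.7)
    expect_true(paste(sort(kept), collapse = ";") %in% terminals)
  }
})
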