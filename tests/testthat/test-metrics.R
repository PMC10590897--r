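cls <- c("tolerant", "moderate", "susceptible")

test_that("perfect agreement gives a diagonal confusion matrix", {
  obs <- rep(cls, c(3, 4, 3))
  cm <- confusion(obs, obs)
  expect_equal(sum(diag(cm$table)), 10)
  expect_equal(sum(cm$table) - sum(diag(cm$table)), 0)
  expect_equal(overall_accuracy(cm), 100)
})

test_that("one-vs-rest bookkeeping for a single misclassification", {
  cm <- confusion("tolerant", "susceptible")
  pc <- cm$per_class
  expect_equal(pc$FN[pc$class == "tolerant"], 1)
  expect_equal(pc$FP[pc$class == "susceptible"], 1)
  expect_equal(pc$TN[pc$class == "moderate"], 1)
})

test_that("confusion requires aligned label vectors", {
  expect_error(confusion(cls, cls[1:2]), "equal length")
  expect_error(confusion("tolerant", "resistant"), "level set")
})

test_that("per-class counts match a brute-force pairwise counter", {
  set.seed(1)
  for (rep in 1:5) {
    obs <- sample(cls, 200, replace = TRUE)
    prd <- sample(cls, 200, replace = TRUE)
    cm <- confusion(obs, prd)
    oracle <- brute_force_counts(obs, prd, cls)
    for (cl in cls) {
      row <- cm$per_class[cm$per_class$class == cl, ]
      expect_identical(c(TP = row$TP, TN = row$TN, FP = row$FP, FN = row$FN),
                       oracle[[cl]])
    }
    # overall accuracy equals direct label comparison
    expect_equal(overall_accuracy(cm), 100 * mean(obs == prd))
  }
})

test_that("class metrics follow the TP/TN/FP/FN formulas", {
  # engineered counts: TP=3, TN=5, FP=1, FN=1 for class tolerant
  obs <- c(rep("tolerant", 4), rep("moderate", 6))
  prd <- c(rep("tolerant", 3), "moderate", "tolerant", rep("moderate", 5))
  cm <- confusion(obs, prd)
  m <- class_metrics(cm, "tolerant")
  expect_equal(unname(m["accuracy"]), 0.8)
  expect_equal(unname(m["precision"]), 0.75)
  expect_equal(unname(m["specificity"]), 5 / 6)
  # never-predicted class: precision undefined, reported as NA sentinel
  cm2 <- confusion(c("tolerant", "moderate"), c("moderate", "moderate"))
  expect_true(is.na(class_metrics(cm2, "tolerant")["precision"]))
  expect_equal(mlgwas:::format_metric(NA_real_), "–")
})

test_that("confusion identities: TP sums, row and column margins", {
  set.seed(2)
  obs <- sample(cls, 150, replace = TRUE)
  prd <- sample(cls, 150, replace = TRUE)
  cm <- confusion(obs, prd)
  expect_equal(sum(cm$per_class$TP), sum(diag(cm$table)))
  for (cl in cls) {
    row <- cm$per_class[cm$per_class$class == cl, ]
    expect_equal(row$TP + row$FN, sum(cm$table[cl, ]))
    expect_equal(row$TP + row$FP, sum(cm$table[, cl]))
    expect_equal(row$TP + row$TN + row$FP + row$FN, cm$n)
  }
})

test_that("overall accuracy is invariant under simultaneous label permutation", {
  set.seed(3)
  obs <- sample(cls, 100, replace = TRUE)
  prd <- sample(cls, 100, replace = TRUE)
  perm <- c(tolerant = "susceptible", moderate = "tolerant",
            susceptible = "moderate")
  expect_equal(overall_accuracy(confusion(obs, prd)),
               overall_accuracy(confusion(perm[obs], perm[prd])))
})

test_that("the marker scan flags strong signals and defines LOD = -log10(p)", {
  expect_equal(-log10(1e-4), 4)  # the flag threshold on the LOD scale
  set.seed(4)
  sim <- simulate_genotypes(50, 20, seed = 4)
  y <- as.numeric(sim$genotypes$dosages[, 7]) * 0.5  # exact linear signal
  res <- single_marker_scan(sim$genotypes, y + rnorm(50, sd = 1e-6))
  expect_true(res$flagged[res$snp_id == "snp_00007"])
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$lod >= 0))
})

test_that("the null scan holds its type-I error near 5%", {
  set.seed(5)
  n <- 50
  X <- matrix(sample(0:2, n * 10000, replace = TRUE), n, 10000,
              dimnames = list(paste0("l", 1:n), paste0("s", 1:10000)))
  y <- rnorm(n)
  res <- single_marker_scan(X, y)
  frac <- mean(res$p < 0.05)
  expect_gte(frac, 0.04)
  expect_lte(frac, 0.06)
})

test_that("zero-variance SNPs are skipped with a log entry", {
  X <- cbind(s1 = c(0, 1, 2, 1, 0, 2), s2 = rep(2, 6))
  rownames(X) <- paste0("l", 1:6)
  expect_message(res <- single_marker_scan(X, rnorm(6)), "zero-variance")
  expect_equal(res$snp_id, "s1")
})

test_that("report bundle is complete, deterministic, and notes skipped stages", {
  toy <- toy_classification(seed = 20)
  spec <- model_spec("random_forest", rf_trees = 100, seed = 21)
  ev <- evaluate_subset(toy$X, toy$classes, c("s1", "s2"), spec)
  tr <- forward_select(toy$X, toy$classes, paste0("s", 1:3), spec, max_iters = 2)
  curve <- overfitting_curve(toy$X, toy$classes, paste0("s", 1:5), spec, c(1, 3))
  sim <- simulate_genotypes(40, 10, seed = 22)
  y <- rnorm(40)
  scan <- single_marker_scan(sim$genotypes, y)
  vips <- compute_vip(fit_pls(impute_mean(sim$genotypes), y, n_components = 2),
                      sim$genotypes$snp_meta)

  d1 <- withr::local_tempdir()
  f1 <- render_reports(d1, vips = vips, thresholded = vips$snp_id[1],
                       pruned = vips$snp_id[1], trace = list(rf = tr),
                       curve = list(rf = curve), scan = scan,
                       cm = ev$confusion)
  expect_true(all(file.exists(f1)))
  expect_true(length(f1) >= 6)
  # every table parses back
  expect_silent(invisible(lapply(grep("csv$", f1, value = TRUE), read.csv)))
  # deterministic: same inputs -> identical bytes
  d2 <- withr::local_tempdir()
  f2 <- render_reports(d2, vips = vips, thresholded = vips$snp_id[1],
                       pruned = vips$snp_id[1], trace = list(rf = tr),
                       curve = list(rf = curve), scan = scan,
                       cm = ev$confusion)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # empty trace: stage noted as skipped
  d3 <- withr::local_tempdir()
  render_reports(d3, vips = vips)
  notes <- readLines(file.path(d3, "run_summary.txt"))
  expect_true(any(grepl("skipped", notes)))
})

test_that("user covariate columns are partialled out of the scan", {
  set.seed(7)
  n <- 60
  cv <- rnorm(n)
  X <- cbind(s1 = sample(0:2, n, TRUE), s2 = sample(0:2, n, TRUE))
  rownames(X) <- paste0("l", 1:n)
  y <- 0.8 * cv + 0.4 * X[, "s1"] + rnorm(n, sd = 0.5)
  res <- single_marker_scan(X, y, covariates = cv)
  # Frisch-Waugh: the partialled scan reproduces the full-model t-test
  ref <- summary(lm(y ~ cv + X[, "s1"]))$coefficients
  expect_equal(res$p[res$snp_id == "s1"], ref[3, 4], tolerance = 1e-8)
})
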