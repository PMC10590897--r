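#' @keywords internal
"_PACKAGE"

# Derive independent sub-seeds from one master seed so that re-simulating one
# artifact (e.g. phenotypes) never perturbs another (genotypes).
derive_seeds <- function(master, n = 2L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

# Plain k-fold assignment (regression CV).
make_folds <- function(n, k) {
  if (k < 2L || k > n) stop("cv folds must be in [2, n]")
  sample(rep_len(seq_len(k), n))
}

# Stratified k-fold assignment: each class spread as evenly as possible across
# folds. If the rarest class has fewer members than k, k is reduced with a
# warning so every fold can hold at least one member of every class.
make_stratified_folds <- function(classes, k) {
  classes <- as.factor(classes)
  min_n <- min(table(classes))
  if (min_n < k) {
    k <- max(2L, as.integer(min_n))
    warning("class with fewer members than requested folds; reducing to ", k,
            " folds", call. = FALSE)
  }
  fold <- integer(length(classes))
  for (cl in levels(classes)) {
    idx <- which(classes == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  structure(fold, k = k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
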