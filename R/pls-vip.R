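#' Fit a PLS1 regression of adjusted scores on SNP dosages
#'
#' NIPALS partial least squares with a single response. Predictor columns
#' are centered and unit-scaled (the usual convention for chip dosages; it
#' makes VIP comparable across MAFs), the response is centered and scaled.
#' The number of components is chosen by k-fold cross-validation of the
#' root-mean-squared error of prediction (RMSEP): the smallest component
#' count whose mean RMSEP is within one standard error of the minimum (the
#' one-standard-error rule), unless a fixed `n_components` is given.
#'
#' @param X numeric matrix, lines x SNPs (mean-impute missing first).
#' @param y numeric response (adjusted damage scores), row-aligned with X.
#' @param max_components largest component count considered; must be
#'   <= min(n_lines - 1, n_snps).
#' @param cv_folds folds for component selection (default 10).
#' @param seed integer controlling the CV fold assignment.
#' @param n_components optional fixed component count (skips CV).
#' @return object of class `pls_fit`: weights `W` (p x A, unit-norm columns),
#'   loadings `P`, response loadings `q`, scores `T`, per-component explained
#'   response sum of squares `ss`, `y_variance_explained`, `cv_error_curve`
#'   (data.frame ncomp/rmsep/se), `n_components`, and the centering/scaling
#'   constants needed by [predict.pls_fit()].
#' @export
fit_pls <- function(X, y, max_components = 10L, cv_folds = 10L, seed = 1L,
                    n_components = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (max_components < 1) stop("max_components must be >= 1")
  if (stats::sd(y) == 0) stop("constant response: PLS undefined")

  if (is.null(n_components)) {
    if (max_components > min(nrow(X) - 1L, ncol(X)))
      stop("max_components must be <= min(n_lines - 1, n_snps)")
    set.seed(seed)
    fold <- make_folds(nrow(X), cv_folds)
    sqerr <- matrix(NA_real_, cv_folds, max_components)
    for (k in seq_len(cv_folds)) {
      tr <- fold != k
      core <- pls1_nipals(X[tr, , drop = FALSE], y[tr], max_components)
      pred <- pls1_predict_all(core, X[!tr, , drop = FALSE])
      if (ncol(pred) < max_components)  # deflation exhausted early in this fold
        pred <- cbind(pred, matrix(pred[, ncol(pred)], nrow(pred),
                                   max_components - ncol(pred)))
      sqerr[k, ] <- colMeans((pred - y[!tr])^2)
    }
    rmsep <- sqrt(colMeans(sqerr))
    se <- apply(sqrt(sqerr), 2, stats::sd) / sqrt(cv_folds)
    best <- which.min(rmsep)
    A <- min(which(rmsep <= rmsep[best] + se[best]))
    cv_curve <- data.frame(ncomp = seq_len(max_components), rmsep = rmsep, se = se)
  } else {
    A <- as.integer(n_components)
    if (A < 1 || A > min(nrow(X) - 1L, ncol(X))) stop("invalid n_components")
    cv_curve <- NULL
  }

  core <- pls1_nipals(X, y, A)
  A <- ncol(core$W)  # may have truncated if the response deflated to zero
  tot_ss <- sum(core$yc^2)
  structure(c(core[c("W", "P", "q", "T", "ss", "x_center", "x_scale",
                     "y_center", "y_scale")],
              list(n_components = A,
                   y_variance_explained = core$ss / tot_ss,
                   cv_error_curve = cv_curve,
                   snp_ids = colnames(X))),
            class = "pls_fit")
}

# NIPALS PLS1 core on centered/scaled data. For a univariate response the
# weight vector of each component is X'y (deflated), normalized; scores are
# mutually orthogonal in regression mode.
pls1_nipals <- function(X, y, A) {
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  x_scale[x_scale == 0] <- 1  # constant columns carry zero weight
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  Xd <- scale(X, x_center, x_scale)
  yc <- (y - y_center) / y_scale
  yd <- yc
  p <- ncol(X)
  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, nrow(X), A)
  q <- ss <- numeric(A)
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {  # response fully deflated; truncate
      A <- a - 1L
      W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
      Tm <- Tm[, seq_len(A), drop = FALSE]; q <- q[seq_len(A)]; ss <- ss[seq_len(A)]
      break
    }
    w <- w / nw
    tsc <- drop(Xd %*% w)
    tt <- sum(tsc^2)
    pv <- drop(crossprod(Xd, tsc)) / tt
    qa <- sum(yd * tsc) / tt
    Xd <- Xd - tcrossprod(tsc, pv)
    yd <- yd - tsc * qa
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- tsc; q[a] <- qa
    ss[a] <- qa^2 * tt
  }
  if (A == 0) stop("no usable PLS component (response orthogonal to predictors)")
  list(W = W, P = P, q = q, T = Tm, ss = ss, yc = yc,
       x_center = x_center, x_scale = x_scale,
       y_center = y_center, y_scale = y_scale)
}

# Predictions at every component count 1..A (columns), original y scale.
pls1_predict_all <- function(core, Xnew) {
  Xs <- scale(Xnew, core$x_center, core$x_scale)
  A <- ncol(core$W)
  R <- core$W %*% solve(crossprod(core$P, core$W))  # W (P'W)^-1
  out <- matrix(0, nrow(Xnew), A)
  for (a in seq_len(A)) {
    B <- R[, seq_len(a), drop = FALSE] %*% core$q[seq_len(a)]
    out[, a] <- drop(Xs %*% B) * core$y_scale + core$y_center
  }
  out
}

#' @export
predict.pls_fit <- function(object, newdata, ncomp = object$n_components, ...) {
  pls1_predict_all(object, as.matrix(newdata))[, ncomp]
}

#' @export
print.pls_fit <- function(x, ...) {
  cat("pls_fit:", length(x$snp_ids), "predictors,", x$n_components, "component(s);",
      sprintf("%.1f%%", 100 * sum(x$y_variance_explained)),
      "of response SS explained\n")
  invisible(x)
}

#' Variable Importance in Projection scores
#'
#' For predictor j over components a = 1..A:
#' VIP_j = sqrt( p * sum_a SS_a * w_ja^2 / sum_a SS_a ), with w_a the
#' unit-norm weight vector of component a and SS_a the response sum of
#' squares explained by that component. By construction the mean of the
#' squared VIP scores over all p predictors equals 1, so a VIP threshold
#' above 1 picks predictors contributing more than an average share to the
#' fitted response index.
#'
#' @param fit a [fit_pls()] result with >= 1 component.
#' @param snp_meta optional data.frame(snp_id, chrom, pos) merged in for
#'   genome-order tie-breaking downstream.
#' @return `vip_table`: data.frame(snp_id, vip, n_components[, chrom, pos]).
#' @export
compute_vip <- function(fit, snp_meta = NULL) {
  stopifnot(inherits(fit, "pls_fit"), fit$n_components >= 1)
  if (sum(fit$ss) <= 0) stop("zero explained response sum of squares")
  p <- nrow(fit$W)
  vip <- sqrt(p * drop(fit$W^2 %*% fit$ss) / sum(fit$ss))
  out <- data.frame(snp_id = fit$snp_ids %||% paste0("snp", seq_len(p)),
                    vip = vip, n_components = fit$n_components,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(snp_meta)) {
    m <- match(out$snp_id, snp_meta$snp_id)
    out$chrom <- snp_meta$chrom[m]
    out$pos <- snp_meta$pos[m]
  }
  class(out) <- c("vip_table", "data.frame")
  out
}

#' Apply the VIP cutoff
#'
#' Keeps exactly the SNPs with VIP >= `cutoff` (default 2.0, the threshold
#' recommended when predictors vastly outnumber observations under strong
#' multicollinearity), sorted by descending VIP; ties broken by ascending
#' (chromosome, position) when metadata is present, else by snp_id.
#'
#' @param vips a [compute_vip()] table.
#' @param cutoff VIP threshold (default 2.0).
#' @return character vector of SNP ids, descending VIP. Empty selection
#'   produces a warning, not an error.
#' @export
threshold_vip <- function(vips, cutoff = 2.0) {
  stopifnot(nrow(vips) > 0)
  keep <- vips[vips$vip >= cutoff, , drop = FALSE]
  if (nrow(keep) == 0) {
    warning("no SNP reaches VIP >= ", cutoff, "; selection is empty", call. = FALSE)
    return(character(0))
  }
  ord <- if (all(c("chrom", "pos") %in% names(keep)))
    order(-keep$vip, keep$chrom, keep$pos)
  else order(-keep$vip, keep$snp_id)
  keep$snp_id[ord]
}

#' Prune correlated SNPs, lowest VIP first
#'
#' Greedy pass over the candidate SNPs in descending VIP order: a SNP is
#' kept iff its absolute Pearson correlation with every already-kept SNP is
#' below `r_cutoff`. Of any correlated pair this discards the lower-VIP
#' member, leaving a kept set whose maximum pairwise |r| is < `r_cutoff`.
#' Zero-variance columns have undefined correlation and are dropped with a
#' message.
#'
#' @param X dosage matrix containing (at least) the candidate columns.
#' @param vips a [compute_vip()] table covering the candidates.
#' @param r_cutoff absolute-correlation threshold (default 0.7).
#' @param snp_subset candidate SNP ids; default = the VIP-thresholded set is
#'   whatever the caller passes, so typically the [threshold_vip()] output.
#' @return character vector of kept SNP ids in descending-VIP order.
#' @export
prune_correlated <- function(X, vips, r_cutoff = 0.7, snp_subset = NULL) {
  X <- as.matrix(X)
  ids <- snp_subset %||% intersect(vips$snp_id, colnames(X))
  if (!all(ids %in% colnames(X))) stop("subset SNPs missing from X")
  if (!all(ids %in% vips$snp_id)) stop("subset SNPs missing from VIP table")
  if (length(ids) == 0) return(character(0))
  v <- vips[match(ids, vips$snp_id), , drop = FALSE]
  ord <- if (all(c("chrom", "pos") %in% names(v)))
    order(-v$vip, v$chrom, v$pos) else order(-v$vip, v$snp_id)
  ids <- ids[ord]
  sds <- apply(X[, ids, drop = FALSE], 2, stats::sd)
  if (any(sds == 0)) {
    message("dropping ", sum(sds == 0), " zero-variance SNP(s): correlation undefined")
    ids <- ids[sds > 0]
  }
  kept <- character(0)
  for (s in ids) {
    if (length(kept) == 0) { kept <- s; next }
    r <- abs(stats::cor(X[, s], X[, kept, drop = FALSE]))
    if (all(r < r_cutoff)) kept <- c(kept, s)
  }
  kept
}
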