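#' Three-class confusion matrix with one-vs-rest bookkeeping
#'
#' Counts by (observed, predicted) pair over the tolerance classes, plus the
#' derived per-class true/false positive/negative counts under the
#' one-vs-rest convention (each class in turn is "positive", the other two
#' pooled as "negative").
#'
#' @param observed,predicted vectors of labels in
#'   \{tolerant, moderate, susceptible\} (or any common level set given via
#'   `levels`).
#' @param levels class levels; defaults to the tolerance classes.
#' @return object of class `confusion_matrix`: list with `table` (rows =
#'   observed, columns = predicted), `per_class` data.frame(class, TP, TN,
#'   FP, FN) and `n`.
#' @export
confusion <- function(observed, predicted, levels = TOLERANCE_LEVELS) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  obs <- factor(as.character(observed), levels = levels)
  prd <- factor(as.character(predicted), levels = levels)
  if (anyNA(obs) || anyNA(prd)) stop("labels outside the declared level set")
  tab <- table(observed = obs, predicted = prd)
  n <- sum(tab)
  per_class <- do.call(rbind, lapply(levels, function(cl) {
    tp <- tab[cl, cl]
    fp <- sum(tab[, cl]) - tp
    fn <- sum(tab[cl, ]) - tp
    tn <- n - tp - fp - fn
    data.frame(class = cl, TP = tp, TN = tn, FP = fp, FN = fn,
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, per_class = per_class, n = n),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(x$table)
  cat(sprintf("overall accuracy: %.1f%%\n", overall_accuracy(x)))
  invisible(x)
}

#' Overall classification accuracy (percent)
#'
#' Number of correct classifications over the total number of samples,
#' times 100.
#'
#' @param cm a [confusion()] matrix.
#' @return percentage in [0, 100].
#' @export
overall_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$n < 1) stop("empty confusion matrix")
  100 * sum(diag(cm$table)) / cm$n
}

#' Per-class accuracy, precision and specificity
#'
#' One-vs-rest metrics for a single class:
#' accuracy = (TP + TN) / (TP + TN + FP + FN), precision = TP / (TP + FP),
#' specificity = TN / (TN + FP). Precision is undefined when the class is
#' never predicted (TP + FP = 0) and is returned as NA (rendered as the
#' dash sentinel in reports).
#'
#' @param cm a [confusion()] matrix.
#' @param class one of the class labels in `cm`.
#' @return named numeric vector (accuracy, precision, specificity).
#' @export
class_metrics <- function(cm, class) {
  stopifnot(inherits(cm, "confusion_matrix"))
  row <- cm$per_class[cm$per_class$class == class, ]
  if (nrow(row) != 1) stop("unknown class: ", class)
  with(row, c(accuracy = (TP + TN) / (TP + TN + FP + FN),
              precision = if (TP + FP == 0) NA_real_ else TP / (TP + FP),
              specificity = TN / (TN + FP)))
}

# All classes at once, one row per class.
all_class_metrics <- function(cm) {
  do.call(rbind, lapply(cm$per_class$class, function(cl) {
    m <- class_metrics(cm, cl)
    data.frame(class = cl, accuracy = m["accuracy"], precision = m["precision"],
               specificity = m["specificity"], row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}

# Dash sentinel for undefined metrics in rendered tables.
format_metric <- function(x, digits = 2) {
  ifelse(is.na(x), "–", formatC(x, digits = digits, format = "f"))
}

#' Single-marker regression scan (comparator)
#'
#' Simple per-SNP linear regression of the adjusted score on the dosage;
#' two-sided p-value from the slope t-test, LOD = -log10(p). SNPs with LOD
#' above `lod_threshold` (default 4.0, the usual marker-trait significance
#' convention) are flagged. This is a plain comparator scan — no kinship or
#' structure correction — intended for Manhattan-style plotting next to the
#' VIP track, not for inference.
#'
#' @param g a [genotype_matrix()] or dosage matrix (missing calls
#'   mean-imputed internally).
#' @param y numeric adjusted scores, row-aligned.
#' @param lod_threshold flag cutoff on the LOD scale.
#' @param covariates optional numeric matrix of user-supplied covariate
#'   columns (none are computed by the package); response and dosages are
#'   residualized on them before the per-SNP regression.
#' @return data.frame(snp_id, chrom, pos, effect, se, p, lod, flagged);
#'   zero-variance SNPs are skipped with a message.
#' @export
single_marker_scan <- function(g, y, lod_threshold = 4.0, covariates = NULL) {
  meta <- if (inherits(g, "genotype_matrix")) g$snp_meta else NULL
  X <- impute_mean(g)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), length(y) >= 3)
  n_cov <- 0L
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    n_cov <- ncol(covariates)
    Q <- qr.Q(qr(cbind(1, covariates)))
    y <- drop(y - Q %*% crossprod(Q, y))
    X <- X - Q %*% crossprod(Q, X)
  }
  n <- length(y)
  sx <- apply(X, 2, stats::sd)
  drop_zv <- sx == 0
  if (any(drop_zv))
    message("skipping ", sum(drop_zv), " zero-variance SNP(s) in scan")
  keep <- which(!drop_zv)
  Xk <- X[, keep, drop = FALSE]
  r <- drop(stats::cor(y, Xk))
  slope <- r * stats::sd(y) / sx[keep]
  df <- n - 2L - n_cov
  tstat <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  p <- pmax(p, .Machine$double.xmin)
  se <- slope / tstat
  out <- data.frame(snp_id = colnames(Xk) %||% paste0("snp", keep),
                    effect = slope, se = se, p = p, lod = -log10(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$flagged <- out$lod > lod_threshold
  if (!is.null(meta)) {
    m <- match(out$snp_id, meta$snp_id)
    out <- cbind(out[, "snp_id", drop = FALSE],
                 chrom = meta$chrom[m], pos = meta$pos[m],
                 out[, setdiff(names(out), "snp_id")])
  }
  out
}
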