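#' Adjust plot-level damage ratings to per-genotype means
#'
#' Fits, by REML, the multi-environment trial model
#' `score ~ 0 + genotype + (1|environment) + (1|environment:replicate) +
#' (1|genotype:environment)` — genotype fixed; environment, replicate nested
#' in environment, and GxE random — and returns the estimated marginal
#' (least-squares) mean per genotype. With genotype as the only fixed term
#' the fixed-effect estimates are exactly the ls-means at equal environment
#' weights, marginal over the random effects; genotypes observed in disjoint
#' environment subsets remain comparable through the shared environment
#' effects. Ratings are treated as numeric: the model is a linear mixed
#' model on the ordinal 1-4 scores, not an ordinal regression.
#'
#' Random terms whose grouping factor has a single level (e.g. one
#' environment) are dropped with a message. Variance components estimated at
#' the zero boundary are flagged.
#'
#' @param ratings data.frame with columns genotype_id, environment_id,
#'   replicate_id, score (see [simulate_phenotypes()] for the layout).
#' @param method "reml" (default) or "balanced", a closed-form fallback for
#'   complete balanced designs where the adjusted mean reduces to the simple
#'   per-genotype arithmetic mean.
#' @param classify if TRUE (default) a tolerance_class column is added via
#'   [classify_tolerance()].
#' @return object of class `adjusted_phenotypes`: data.frame(genotype_id,
#'   adjusted_score, tolerance_class) with attributes `varcomp` (named
#'   variance components, residual included), `boundary` (components pinned
#'   at zero) and `method`.
#' @export
fit_adjusted_means <- function(ratings, method = c("reml", "balanced"),
                               classify = TRUE) {
  method <- match.arg(method)
  need <- c("genotype_id", "environment_id", "replicate_id", "score")
  stopifnot(all(need %in% names(ratings)))
  ratings <- as.data.frame(ratings)
  if (length(unique(ratings$genotype_id)) < 2) stop("need >= 2 genotypes")
  if (anyNA(ratings$score)) stop("missing scores not supported")

  if (method == "balanced") {
    tab <- table(ratings$genotype_id, ratings$environment_id, ratings$replicate_id)
    if (length(unique(as.vector(tab))) != 1)
      stop("design is not complete and balanced; use method = \"reml\"")
    means <- tapply(ratings$score, ratings$genotype_id, mean)
    out <- data.frame(genotype_id = names(means), adjusted_score = as.numeric(means),
                      stringsAsFactors = FALSE)
    varcomp <- NULL
    boundary <- character(0)
  } else {
    d <- data.frame(genotype = factor(ratings$genotype_id),
                    environment = factor(ratings$environment_id),
                    replicate = factor(ratings$replicate_id),
                    score = as.numeric(ratings$score))
    terms <- c("(1 | environment)", "(1 | environment:replicate)",
               "(1 | genotype:environment)")
    drop_term <- c(nlevels(d$environment) < 2,
                   nlevels(d$environment) * nlevels(d$replicate) < 2,
                   nlevels(d$environment) < 2)
    if (any(drop_term))
      message("dropping random term(s) with a single level: ",
              paste(terms[drop_term], collapse = ", "))
    terms <- terms[!drop_term]
    if (!length(terms)) stop("no random terms left; need >= 2 environments")
    form <- stats::as.formula(paste("score ~ 0 + genotype +", paste(terms, collapse = " + ")))
    fit <- tryCatch(
      lme4::lmer(form, data = d, REML = TRUE,
                 control = lme4::lmerControl(
                   check.conv.singular = "ignore",
                   optCtrl = list(ftol_abs = 1e-8, xtol_abs = 1e-8, maxeval = 2000))),
      error = function(e) stop("mixed model failed to converge: ",
                               conditionMessage(e), call. = FALSE))
    b <- lme4::fixef(fit)
    names(b) <- sub("^genotype", "", names(b))
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp <- stats::setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual", vc$grp))
    boundary <- names(varcomp)[varcomp < 1e-8 & names(varcomp) != "residual"]
    if (length(boundary))
      message("variance component(s) at the zero boundary: ",
              paste(boundary, collapse = ", "))
    out <- data.frame(genotype_id = names(b), adjusted_score = as.numeric(b),
                      stringsAsFactors = FALSE)
    out <- out[order(out$genotype_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (classify) out$tolerance_class <- classify_tolerance(out$adjusted_score)
  structure(out, varcomp = varcomp, boundary = boundary, method = method,
            class = c("adjusted_phenotypes", "data.frame"))
}

#' Tolerance class from an adjusted damage score
#'
#' tolerant: score <= 2; moderate: 2 < score <= 3; susceptible: score > 3.
#' Scores outside the 1-4 rating scale trigger a warning and are clamped
#' before classification.
#'
#' @param score numeric vector of adjusted damage scores.
#' @return factor with levels tolerant, moderate, susceptible.
#' @export
classify_tolerance <- function(score) {
  stopifnot(is.numeric(score), all(is.finite(score)))
  if (any(score < 1 | score > 4)) {
    warning("score(s) outside the 1-4 rating scale; clamped for classification",
            call. = FALSE)
    score <- pmin(pmax(score, 1), 4)
  }
  cls <- cut(score, breaks = c(-Inf, 2, 3, Inf),
             labels = c("tolerant", "moderate", "susceptible"), right = TRUE)
  factor(as.character(cls), levels = TOLERANCE_LEVELS)
}

#' @rdname classify_tolerance
#' @format NULL
#' @export
TOLERANCE_LEVELS <- c("tolerant", "moderate", "susceptible")

#' Write adjusted phenotypes and the variance-component report
#' @param adj an `adjusted_phenotypes` object.
#' @param csv_path output CSV (genotype, adjusted_score, class).
#' @param report_path optional text report of the variance components.
#' @export
write_adjusted <- function(adj, csv_path, report_path = NULL) {
  utils::write.csv(as.data.frame(adj), csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(report_path)) {
    vc <- attr(adj, "varcomp")
    lines <- c("Variance components (REML)",
               if (is.null(vc)) "  (balanced closed-form fit: none estimated)"
               else sprintf("  %-24s %.6f", names(vc), vc),
               if (length(attr(adj, "boundary")))
                 paste("  at zero boundary:", paste(attr(adj, "boundary"), collapse = ", ")))
    writeLines(lines, report_path)
  }
  invisible(csv_path)
}
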