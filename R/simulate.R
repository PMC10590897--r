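#' Simulation ground truth
#'
#' Bookkeeping object for a synthetic genotype/phenotype experiment: which
#' SNPs carry planted QTL, their additive effects on the latent liability,
#' the variance components of the multi-environment trial, and the
#' breakpoints that bin the liability onto the 1-4 visual damage grid.
#'
#' @param qtl_snp_ids character vector of QTL SNP ids (may be empty).
#' @param qtl_effects numeric additive effect per QTL on the liability scale.
#' @param variance_components named numeric vector with elements `genotype`
#'   (polygenic background), `environment`, `gxe`, `replicate` (nested in
#'   environment) and `residual`; all >= 0.
#' @param liability_breakpoints strictly increasing numeric vector of length 6
#'   cutting the liability into the seven ratings 1.0, 1.5, ..., 4.0.
#' @param seed master integer seed; two independent sub-streams (genotypes,
#'   phenotypes) are derived from it so re-simulating phenotypes never
#'   perturbs the genotypes.
#' @return object of class `simulation_truth`.
#' @export
simulation_truth <- function(qtl_snp_ids = character(),
                             qtl_effects = numeric(),
                             variance_components = c(genotype = 0.1, environment = 0.25,
                                                     gxe = 0.1, replicate = 0.05,
                                                     residual = 0.5),
                             liability_breakpoints = NULL,
                             seed = 1L) {
  stopifnot(length(qtl_snp_ids) == length(qtl_effects))
  need <- c("genotype", "environment", "gxe", "replicate", "residual")
  if (!all(need %in% names(variance_components)))
    stop("variance_components must be named: ", paste(need, collapse = ", "))
  variance_components <- variance_components[need]
  if (any(variance_components < 0)) stop("variances must be >= 0")
  if (!is.null(liability_breakpoints)) {
    stopifnot(length(liability_breakpoints) == 6)
    if (is.unsorted(liability_breakpoints, strictly = TRUE))
      stop("liability_breakpoints must be strictly increasing")
  }
  seeds <- derive_seeds(seed, 2L)
  structure(list(qtl_snp_ids = as.character(qtl_snp_ids),
                 qtl_effects = as.numeric(qtl_effects),
                 variance_components = variance_components,
                 liability_breakpoints = liability_breakpoints,
                 seed = as.integer(seed),
                 seed_genotypes = seeds[1], seed_phenotypes = seeds[2]),
            class = "simulation_truth")
}

# The rating grid used throughout: 1-4 visual damage scale in 0.5 increments.
RATING_GRID <- seq(1, 4, by = 0.5)

# Default liability breakpoints: bin probabilities chosen so that a Gaussian
# liability yields roughly a 19% tolerant (rating <= 2) / 62% moderate
# (2 < rating <= 3) / 19% susceptible (rating > 3) class mix, the mix
# typically seen in advanced breeding panels under prolonged off-target
# dicamba exposure.
default_breakpoints <- function(mean = 0, sd = 1) {
  probs <- c(0.04, 0.06, 0.09, 0.31, 0.31, 0.13, 0.06)
  mean + stats::qnorm(cumsum(probs[-length(probs)])) * sd
}

#' Simulate LD-blocked biallelic genotypes
#'
#' Generates a lines x SNPs minor-allele dosage matrix for an inbred panel.
#' SNPs are laid out in consecutive blocks along chromosomes; within a block,
#' haplotype alleles are drawn from a Gaussian copula with AR(1) correlation
#' (adjacent SNPs most correlated), while different blocks are independent —
#' a cheap approximation to chip-scale linkage disequilibrium. Lines are
#' fully inbred by default (a single haplotype doubled, dosages 0/2); a
#' heterozygosity option draws two independent haplotypes instead.
#'
#' Blocks whose realized MAF falls below the lower bound of `maf_range` are
#' redrawn (the panel emulates a chip already filtered at MAF >= 0.05).
#'
#' Optionally plants QTL: `n_qtl_large` large-effect loci (sampled among SNPs
#' with MAF >= 0.2, mirroring the intermediate-frequency major loci that
#' dominate tolerance) and `n_qtl_small` small-effect loci, at most one QTL
#' per LD block.
#'
#' @param n_lines,n_snps panel dimensions (n_lines >= 2, n_snps >= 1).
#' @param n_chromosomes chromosomes the SNPs are spread over (soybean: 20).
#' @param block_size SNPs per LD block.
#' @param within_block_corr latent AR(1) correlation between adjacent SNPs in
#'   a block, in [0, 1).
#' @param maf_range interval within (0, 0.5] from which target MAFs are drawn;
#'   realized MAFs are guaranteed >= its lower bound.
#' @param heterozygosity 0 (default, fully inbred) or 1: with 1, two
#'   independent haplotypes per line allow dosage 1.
#' @param n_qtl_large,n_qtl_small number of planted large/small-effect QTL.
#' @param effect_large,effect_small absolute additive effect sizes on the
#'   liability scale (signs drawn at random).
#' @param variance_components passed to [simulation_truth()].
#' @param liability_breakpoints optional; if NULL, defaults are placed so the
#'   total (QTL + polygenic + trial) liability variance maps onto the usual
#'   tolerant/moderate/susceptible mix.
#' @param seed master seed.
#' @return list with elements `genotypes` ([genotype_matrix()]) and `truth`
#'   ([simulation_truth()]).
#' @export
simulate_genotypes <- function(n_lines, n_snps, n_chromosomes = 20L,
                               block_size = 10L, within_block_corr = 0.9,
                               maf_range = c(0.05, 0.5),
                               heterozygosity = 0,
                               n_qtl_large = 0L, n_qtl_small = 0L,
                               effect_large = 0.6, effect_small = 0.15,
                               variance_components = c(genotype = 0.1, environment = 0.25,
                                                       gxe = 0.1, replicate = 0.05,
                                                       residual = 0.5),
                               liability_breakpoints = NULL,
                               seed = 1L) {
  stopifnot(n_lines >= 2, n_snps >= 1,
            within_block_corr >= 0, within_block_corr < 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  n_hap_draws <- if (heterozygosity > 0) 2L * n_lines else n_lines
  # coarse feasibility check: the lowest non-zero MAF representable
  if (maf_range[1] > 0.45 && n_lines < 20)
    stop("maf_range lower bound ", maf_range[1], " unreachable at n_lines = ", n_lines)

  truth <- simulation_truth(variance_components = variance_components,
                            liability_breakpoints = liability_breakpoints,
                            seed = seed)
  set.seed(truth$seed_genotypes)

  n_chromosomes <- min(n_chromosomes, n_snps)
  chrom_of <- sort(rep_len(seq_len(n_chromosomes), n_snps))
  snp_ids <- sprintf("snp_%05d", seq_len(n_snps))
  pos <- unlist(lapply(split(seq_len(n_snps), chrom_of),
                       function(i) cumsum(sample(1e4:1e5, length(i), replace = TRUE))),
                use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  snp_meta <- data.frame(snp_id = snp_ids, chrom = chrom_of, pos = pos,
                         ref = ref, alt = alt, stringsAsFactors = FALSE)

  # block index: consecutive runs of block_size within a chromosome
  block_of <- unlist(lapply(split(seq_len(n_snps), chrom_of), function(i)
    paste0(chrom_of[i[1]], "_", ceiling(seq_along(i) / block_size))), use.names = FALSE)

  draw_block <- function(m) {
    # m SNPs, AR(1) latent correlation; returns n_hap_draws x m 0/1 haplotypes
    # and the target MAFs used
    target <- stats::runif(m, maf_range[1], maf_range[2])
    z <- matrix(stats::rnorm(n_hap_draws * m), n_hap_draws, m)
    if (m > 1 && within_block_corr > 0) {
      r <- within_block_corr
      for (j in 2:m) z[, j] <- r * z[, j - 1] + sqrt(1 - r^2) * z[, j]
    }
    hap <- sweep(z, 2, stats::qnorm(target), "<") * 1L
    hap
  }

  dosages <- matrix(0L, n_lines, n_snps,
                    dimnames = list(sprintf("line_%04d", seq_len(n_lines)), snp_ids))
  for (b in unique(block_of)) {
    cols <- which(block_of == b)
    ok <- FALSE
    for (try in seq_len(200L)) {
      hap <- draw_block(length(cols))
      d <- if (heterozygosity > 0) hap[seq_len(n_lines), , drop = FALSE] +
             hap[n_lines + seq_len(n_lines), , drop = FALSE]
           else 2L * hap
      f <- colMeans(d) / 2
      flip <- f > 0.5
      d[, flip] <- 2L - d[, flip, drop = FALSE]
      maf <- pmin(f, 1 - f)
      if (all(maf >= maf_range[1])) { ok <- TRUE; break }
    }
    if (!ok)
      stop("could not realize MAF >= ", maf_range[1], " for block ", b,
           " (", length(cols), " SNPs) at n_lines = ", n_lines,
           "; widen maf_range or increase n_lines")
    dosages[, cols] <- d
  }

  geno <- genotype_matrix(dosages, snp_meta)

  n_qtl <- n_qtl_large + n_qtl_small
  if (n_qtl > 0) {
    eligible_large <- snp_ids[geno$maf >= 0.2]
    if (length(eligible_large) < n_qtl_large)
      stop("not enough SNPs with MAF >= 0.2 to plant ", n_qtl_large, " large-effect QTL")
    # at most one QTL per block where possible, large-effect loci first
    pick <- character(0)
    used_blocks <- character(0)
    pool_order <- c(sample(eligible_large), sample(setdiff(snp_ids, eligible_large)))
    for (s in pool_order) {
      b <- block_of[match(s, snp_ids)]
      if (b %in% used_blocks) next
      pick <- c(pick, s); used_blocks <- c(used_blocks, b)
      if (length(pick) == n_qtl) break
    }
    if (length(pick) < n_qtl) pick <- c(pick, sample(setdiff(snp_ids, pick), n_qtl - length(pick)))
    large <- pick[seq_len(n_qtl_large)]
    small <- setdiff(pick, large)
    # ensure large-effect picks really are intermediate-frequency
    large <- c(intersect(large, eligible_large),
               sample(setdiff(eligible_large, pick),
                      n_qtl_large - length(intersect(large, eligible_large))))
    effects <- c(rep(effect_large, length(large)), rep(effect_small, length(small))) *
      sample(c(-1, 1), n_qtl, replace = TRUE)
    truth$qtl_snp_ids <- c(large, small)
    truth$qtl_effects <- effects
  }

  if (is.null(truth$liability_breakpoints)) {
    qtl_var <- if (n_qtl > 0)
      stats::var(drop(geno$dosages[, truth$qtl_snp_ids, drop = FALSE] %*% truth$qtl_effects))
    else 0
    qtl_mean <- if (n_qtl > 0)
      mean(drop(geno$dosages[, truth$qtl_snp_ids, drop = FALSE] %*% truth$qtl_effects))
    else 0
    tot <- qtl_var + sum(truth$variance_components)
    truth$liability_breakpoints <- default_breakpoints(qtl_mean, sqrt(max(tot, 1e-12)))
  }
  list(genotypes = geno, truth = truth)
}

#' Simulate plot-level ordinal damage ratings
#'
#' Draws one rating per line x environment x replicate from the liability
#' model: liability = QTL additive values + polygenic line effect +
#' environment effect + GxE effect + replicate-within-environment effect +
#' residual, each component Gaussian with the variance recorded in `truth`.
#' The liability is binned by `truth$liability_breakpoints` onto the damage
#' grid 1.0, 1.5, ..., 4.0.
#'
#' @param genotypes a [genotype_matrix()] (or the list returned by
#'   [simulate_genotypes()]).
#' @param truth a [simulation_truth()]; its QTL ids must exist in `genotypes`.
#' @param n_envs,n_reps environments and replicates per environment (the field
#'   study design: nine environments, three-replicate RCBD).
#' @param return_liability if TRUE a `liability` column with the continuous
#'   latent value is included (debugging/variance accounting).
#' @return data.frame with columns genotype_id, environment_id, replicate_id,
#'   score (and optionally liability); rows ordered lines-fastest within
#'   replicate within environment.
#' @export
simulate_phenotypes <- function(genotypes, truth, n_envs = 9L, n_reps = 3L,
                                return_liability = FALSE) {
  if (is.list(genotypes) && !inherits(genotypes, "genotype_matrix") &&
      !is.null(genotypes$genotypes)) {
    if (missing(truth)) truth <- genotypes$truth
    genotypes <- genotypes$genotypes
  }
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(truth, "simulation_truth"),
            n_envs >= 1, n_reps >= 1)
  dos <- genotypes$dosages
  if (nrow(dos) == 0 || ncol(dos) == 0) stop("empty genotype matrix")
  if (!all(truth$qtl_snp_ids %in% colnames(dos)))
    stop("truth QTL ids absent from genotype matrix")

  set.seed(truth$seed_phenotypes)
  vc <- truth$variance_components
  n_lines <- nrow(dos)
  g_qtl <- if (length(truth$qtl_snp_ids))
    drop(dos[, truth$qtl_snp_ids, drop = FALSE] %*% truth$qtl_effects) else numeric(n_lines)
  g_poly <- stats::rnorm(n_lines, 0, sqrt(vc["genotype"]))
  env_eff <- stats::rnorm(n_envs, 0, sqrt(vc["environment"]))
  gxe_eff <- matrix(stats::rnorm(n_lines * n_envs, 0, sqrt(vc["gxe"])), n_lines, n_envs)
  rep_eff <- matrix(stats::rnorm(n_envs * n_reps, 0, sqrt(vc["replicate"])), n_envs, n_reps)

  env_id <- rep(seq_len(n_envs), each = n_reps * n_lines)
  rep_id <- rep(rep(seq_len(n_reps), each = n_lines), times = n_envs)
  line_i <- rep(seq_len(n_lines), times = n_envs * n_reps)
  liability <- (g_qtl + g_poly)[line_i] + env_eff[env_id] +
    gxe_eff[cbind(line_i, env_id)] + rep_eff[cbind(env_id, rep_id)] +
    stats::rnorm(n_lines * n_envs * n_reps, 0, sqrt(vc["residual"]))
  score <- RATING_GRID[findInterval(liability, truth$liability_breakpoints) + 1L]
  out <- data.frame(genotype_id = rownames(dos)[line_i],
                    environment_id = paste0("env_", env_id),
                    replicate_id = rep_id,
                    score = score,
                    stringsAsFactors = FALSE)
  if (return_liability) out$liability <- liability
  out
}
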