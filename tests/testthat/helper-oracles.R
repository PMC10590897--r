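# Independent oracles, coded separately from the package internals.

# Brute-force one-vs-rest confusion counter: plain loops over label pairs.
brute_force_counts <- function(obs, prd, levels) {
  out <- list()
  for (cl in levels) {
    tp <- tn <- fp <- fn <- 0L
    for (i in seq_along(obs)) {
      o_pos <- obs[i] == cl
      p_pos <- prd[i] == cl
      if (o_pos && p_pos) tp <- tp + 1L
      else if (!o_pos && !p_pos) tn <- tn + 1L
      else if (!o_pos && p_pos) fp <- fp + 1L
      else fn <- fn + 1L
    }
    out[[cl]] <- c(TP = tp, TN = tn, FP = fp, FN = fn)
  }
  out
}

# Direct evaluation of the VIP formula from a fitted object's components,
# written as an explicit double loop rather than matrix algebra.
vip_direct <- function(fit) {
  p <- nrow(fit$W)
  A <- ncol(fit$W)
  tot <- sum(fit$ss)
  vip <- numeric(p)
  for (j in seq_len(p)) {
    acc <- 0
    for (a in seq_len(A)) {
      w_norm <- sqrt(sum(fit$W[, a]^2))
      acc <- acc + fit$ss[a] * (fit$W[j, a] / w_norm)^2
    }
    vip[j] <- sqrt(p * acc / tot)
  }
  vip
}

# Exhaustive enumeration of every kept-set reachable under the rule "while a
# pair with |r| >= cutoff exists, discard its lower-VIP member" (VIP ties
# broken by id order). Returns the terminal states as a character vector of
# sorted, ";"-collapsed kept sets.
prune_terminal_states <- function(R, vip, cutoff = 0.7) {
  ids <- names(vip)
  seen <- new.env(hash = TRUE)
  terminals <- character(0)
  explore <- function(keep) {
    key <- paste(sort(keep), collapse = ";")
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    viol <- list()
    if (length(keep) > 1) {
      cmb <- utils::combn(keep, 2)
      for (c_i in seq_len(ncol(cmb))) {
        a <- cmb[1, c_i]; b <- cmb[2, c_i]
        if (abs(R[a, b]) >= cutoff) viol[[length(viol) + 1]] <- c(a, b)
      }
    }
    if (!length(viol)) {
      terminals <<- union(terminals, key)
      return(invisible())
    }
    for (pair in viol) {
      lower <- if (vip[pair[1]] < vip[pair[2]]) pair[1]
        else if (vip[pair[2]] < vip[pair[1]]) pair[2]
        else sort(pair)[2]
      explore(setdiff(keep, lower))
    }
  }
  explore(ids)
  terminals
}

# Method-of-moments variance-component recovery for the balanced liability
# model, with finite-sample cross-contamination corrections.
mom_varcomp <- function(liability, n_lines, n_reps, n_envs) {
  arr <- array(liability, dim = c(n_lines, n_reps, n_envs))  # [line, rep, env]
  I <- n_lines; R <- n_reps; J <- n_envs
  grand <- mean(arr)
  m_jr <- apply(arr, c(2, 3), mean)            # rep-within-env means (R x J)
  m_j <- colMeans(m_jr)                        # env means
  m_ij <- apply(arr, c(1, 3), mean)            # cell means (I x J)
  m_i <- rowMeans(m_ij)                        # line means
  # residual: within-cell, rep effect removed
  resid <- sweep(arr, c(1, 3), m_ij) -
    rep(sweep(m_jr, 2, m_j), each = I)
  var_eps <- sum(resid^2) / (J * (I - 1) * (R - 1))
  # interaction
  int <- m_ij - outer(m_i, rep(1, J)) - outer(rep(1, I), m_j) + grand
  var_gxe <- sum(int^2) / ((I - 1) * (J - 1)) - var_eps / R
  var_rep <- mean(apply(m_jr, 2, stats::var)) - var_eps / I
  var_env <- stats::var(m_j) - var_gxe / I - var_rep / R - var_eps / (I * R)
  var_gen <- stats::var(m_i) - var_gxe / J - var_eps / (J * R)
  c(genotype = var_gen, environment = var_env, gxe = var_gxe,
    replicate = var_rep, residual = var_eps)
}

# A small hand-rolled VCF fixture writer.
write_test_vcf <- function(path, records, samples) {
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               records), path)
  path
}
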