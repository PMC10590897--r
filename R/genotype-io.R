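#' Read genotypes from VCF or dosage CSV
#'
#' VCF records are restricted to biallelic SNPs (multi-allelic records are
#' dropped with a message giving the count). GT calls are converted to ALT
#' allele counts and then re-oriented so dosages count the minor allele,
#' recomputed from the data itself rather than trusting ref/alt order.
#'
#' The dosage-CSV dialect: header row of SNP ids, first column the line id,
#' cells 0/1/2 or empty for missing. SNP metadata (chrom/pos/ref/alt) may be
#' supplied as a sidecar TSV via `meta_path`; without it, placeholder
#' metadata (single chromosome, index positions) is attached.
#'
#' @param path input file.
#' @param format "vcf", "dosage" or "auto" (by file extension).
#' @param meta_path optional SNP metadata TSV (snp_id, chrom, pos, ref, alt)
#'   for dosage-CSV input.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage"), meta_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_dosage(path, meta_path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "REF"]) != 1 | nchar(fix[, "ALT"]) != 1
  if (any(multi))
    message("dropped ", sum(multi), " multi-allelic or non-SNP record(s)")
  if (all(multi)) stop("zero biallelic SNPs after parsing ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  # ALT allele count from GT strings ("0/1", "1|1", ".", "./.")
  alt_count <- function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_integer_)
    a <- strsplit(s, "[/|]")[[1]]
    if (any(a == ".")) return(NA_integer_)
    sum(a == "1")
  }
  ac <- vapply(as.vector(gt), alt_count, integer(1), USE.NAMES = FALSE)
  dos <- t(matrix(ac, nrow = nrow(gt), ncol = ncol(gt)))  # lines x snps
  rownames(dos) <- colnames(gt)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  colnames(dos) <- ids
  # orient to minor allele
  f <- colMeans(dos, na.rm = TRUE) / 2
  flip <- !is.na(f) & f > 0.5
  dos[, flip] <- 2L - dos[, flip, drop = FALSE]
  meta <- data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  genotype_matrix(dos, meta)
}

read_genotypes_dosage <- function(path, meta_path = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("dosage CSV must have a line-id column plus >= 1 SNP column")
  line_ids <- as.character(tab[[1]])
  dos <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(dos) <- "integer"
  rownames(dos) <- line_ids
  if (ncol(dos) == 0) stop("zero SNPs after parsing ", path)
  bad <- which(!(dos %in% c(0L, 1L, 2L) | is.na(dos)))
  if (length(bad))
    stop("malformed dosage value at data row ",
         ((bad[1] - 1) %% nrow(dos)) + 1, " of ", path)
  # orient to minor allele
  f <- colMeans(dos, na.rm = TRUE) / 2
  flip <- !is.na(f) & f > 0.5
  dos[, flip] <- 2L - dos[, flip, drop = FALSE]
  if (!is.null(meta_path)) {
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    meta <- meta[match(colnames(dos), meta$snp_id), , drop = FALSE]
    if (anyNA(meta$snp_id)) stop("metadata TSV missing entries for some SNPs")
  } else {
    meta <- data.frame(snp_id = colnames(dos), chrom = 1L,
                       pos = seq_len(ncol(dos)), ref = "A", alt = "C",
                       stringsAsFactors = FALSE)
  }
  genotype_matrix(dos, meta)
}

#' Write genotypes as a dosage CSV
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @export
write_dosage_csv <- function(g, path) {
  tab <- data.frame(line_id = rownames(g$dosages), g$dosages,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write SNP metadata as a TSV sidecar
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @export
write_snp_meta <- function(g, path) {
  utils::write.table(g$snp_meta, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write genotypes as VCF v4.2
#'
#' One sample per line, GT field only. Dosages are written on the recorded
#' ref/alt orientation with the minor allele as ALT (dosage d becomes the
#' genotype with d ALT alleles; phase unknown, "/" separator).
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=mlgwas",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(g$dosages)), collapse = "\t"), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(ncol(g$dosages))) {
    d <- g$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    m <- g$snp_meta[j, ]
    writeLines(paste(c(m$chrom, m$pos, m$snp_id, m$ref, m$alt, ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Per-SNP minor allele frequency
#'
#' MAF = min(f, 1 - f) with f = (sum of dosages) / (2 x non-missing lines);
#' missing calls are excluded from numerator and denominator. SNPs with all
#' calls missing get MAF NA and are flagged.
#'
#' @param g a [genotype_matrix()] or a dosage matrix.
#' @return data.frame(snp_id, n_called, maf, all_missing).
#' @export
compute_maf <- function(g) {
  dos <- if (inherits(g, "genotype_matrix")) g$dosages else as.matrix(g)
  n_called <- colSums(!is.na(dos))
  f <- colSums(dos, na.rm = TRUE) / (2 * n_called)
  maf <- pmin(f, 1 - f)
  maf[n_called == 0] <- NA_real_
  if (any(n_called == 0))
    warning(sum(n_called == 0), " SNP(s) with all calls missing: MAF undefined",
            call. = FALSE)
  data.frame(snp_id = colnames(dos) %||% paste0("snp", seq_along(maf)),
             n_called = n_called, maf = as.numeric(maf),
             all_missing = n_called == 0, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Filter SNPs on minor allele frequency
#'
#' Retains exactly the SNPs with MAF >= `threshold` (the study design drops
#' MAF < 0.05, so a SNP at exactly the threshold is kept). Column order is
#' preserved; the number removed is attached as attribute `n_removed`.
#'
#' @param g a [genotype_matrix()].
#' @param threshold frequency cutoff, default 0.05.
#' @return filtered [genotype_matrix()] with attribute `n_removed`.
#' @export
filter_maf <- function(g, threshold = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  keep <- !is.na(g$maf) & g$maf >= threshold
  if (!any(keep))
    stop("all ", length(keep), " SNPs removed at MAF threshold ", threshold,
         "; review the threshold")
  out <- genotype_matrix(g$dosages[, keep, drop = FALSE],
                         g$snp_meta[keep, , drop = FALSE])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Mean-impute missing dosages
#'
#' Missing calls are replaced by the per-SNP mean dosage (the simplest
#' deterministic choice for downstream modelling); the number of imputed
#' cells is reported via a message.
#'
#' @param g a [genotype_matrix()] or dosage matrix.
#' @return numeric dosage matrix with no missing values.
#' @export
impute_mean <- function(g) {
  dos <- if (inherits(g, "genotype_matrix")) g$dosages else as.matrix(g)
  storage.mode(dos) <- "double"
  n_miss <- sum(is.na(dos))
  if (n_miss > 0) {
    mu <- colMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- mu[idx[, 2]]
    message("mean-imputed ", n_miss, " missing dosage call(s)")
  }
  dos
}
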