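#' Construct a genotype matrix object
#'
#' Container for a lines x SNPs minor-allele dosage matrix plus per-SNP
#' metadata and minor-allele frequencies. Dosages are 0/1/2 counts of the
#' minor allele (NA = missing call). MAF is recomputed from the dosages on
#' construction, so the minor-allele orientation always reflects the data at
#' hand, not the file's ref/alt order.
#'
#' @param dosages integer matrix, lines in rows, SNPs in columns; values in
#'   \{0, 1, 2\} or NA. Row and column names are the line and SNP ids.
#' @param snp_meta data.frame with columns snp_id, chrom, pos, ref, alt; one
#'   row per column of `dosages`, in the same order.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `snp_meta` and `maf` (named numeric vector, values <= 0.5).
#' @export
genotype_matrix <- function(dosages, snp_meta) {
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages))) stop("dosage matrix must have SNP column names")
  if (is.null(rownames(dosages))) rownames(dosages) <- paste0("line_", seq_len(nrow(dosages)))
  if (anyDuplicated(colnames(dosages))) stop("duplicate snp ids in dosage matrix")
  stopifnot(is.data.frame(snp_meta),
            all(c("snp_id", "chrom", "pos") %in% names(snp_meta)),
            nrow(snp_meta) == ncol(dosages))
  if (!identical(as.character(snp_meta$snp_id), colnames(dosages)))
    stop("snp_meta rows must match dosage columns in order")
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  # positions non-decreasing within each chromosome
  for (ch in unique(snp_meta$chrom)) {
    p <- snp_meta$pos[snp_meta$chrom == ch]
    if (is.unsorted(p)) stop("positions must be non-decreasing within chromosome ", ch)
  }
  g <- structure(list(dosages = dosages, snp_meta = snp_meta, maf = NULL),
                 class = "genotype_matrix")
  g$maf <- compute_maf(g)$maf
  names(g$maf) <- colnames(dosages)
  g
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "lines x", ncol(x$dosages), "SNPs\n")
  cat("  chromosomes:", length(unique(x$snp_meta$chrom)),
      " | MAF range:", sprintf("%.3f-%.3f", min(x$maf, na.rm = TRUE), max(x$maf, na.rm = TRUE)),
      " | missing calls:", sum(is.na(x$dosages)), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# Subset SNP columns, keeping metadata and MAF in step.
subset_snps <- function(g, snp_ids) {
  keep <- match(snp_ids, colnames(g$dosages))
  if (anyNA(keep)) stop("unknown snp ids: ", paste(snp_ids[is.na(keep)], collapse = ", "))
  genotype_matrix(g$dosages[, keep, drop = FALSE],
                  g$snp_meta[keep, , drop = FALSE])
}
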