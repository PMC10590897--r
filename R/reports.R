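#' Assemble the VIP Manhattan table
#'
#' One row per SNP with its genome coordinates, VIP score and whether it
#' survived the VIP threshold and the correlation pruning — directly
#' plottable as a VIP Manhattan track.
#'
#' @param vips a [compute_vip()] table (with chrom/pos merged in).
#' @param thresholded SNP ids kept by [threshold_vip()].
#' @param pruned SNP ids kept by [prune_correlated()].
#' @return data.frame(snp_id, chrom, pos, vip, kept_after_threshold,
#'   kept_after_pruning).
#' @export
vip_report_table <- function(vips, thresholded = character(0), pruned = character(0)) {
  data.frame(snp_id = vips$snp_id,
             chrom = vips$chrom %||% NA, pos = vips$pos %||% NA,
             vip = vips$vip,
             kept_after_threshold = vips$snp_id %in% thresholded,
             kept_after_pruning = vips$snp_id %in% pruned,
             stringsAsFactors = FALSE)
}

#' Write the report bundle
#'
#' Emits a deterministic set of CSV/text files: the VIP Manhattan table, the
#' per-iteration stepwise trace (metrics stored at full precision; a
#' 2-decimal formatted text rendering with the dash sentinel for undefined
#' precision accompanies it), the overfitting curve, the single-marker scan
#' table and the pooled confusion matrix. Stages whose artifact is NULL or
#' empty are noted as skipped in the summary.
#'
#' @param dir output directory (created if missing).
#' @param vips optional [vip_report_table()] input (a vip_table plus kept
#'   sets, see `thresholded`/`pruned`).
#' @param thresholded,pruned kept-SNP id vectors for the VIP table flags.
#' @param trace optional [forward_select()] trace (or named list of traces,
#'   one per model family).
#' @param curve optional [overfitting_curve()] table (or named list).
#' @param scan optional [single_marker_scan()] table.
#' @param cm optional [confusion()] matrix.
#' @return invisible character vector of files written.
#' @export
render_reports <- function(dir, vips = NULL, thresholded = character(0),
                           pruned = character(0), trace = NULL, curve = NULL,
                           scan = NULL, cm = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  notes <- character(0)
  wcsv <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.csv(x, p, row.names = FALSE, quote = FALSE, na = "")
    written <<- c(written, p)
  }

  if (!is.null(vips) && nrow(vips) > 0) {
    wcsv(vip_report_table(vips, thresholded, pruned), "vip_table.csv")
  } else notes <- c(notes, "VIP stage skipped (no table)")

  traces <- if (inherits(trace, "step_trace")) list(model = trace) else trace
  if (length(traces)) {
    for (nm in names(traces)) {
      tr <- traces[[nm]]
      if (is.null(tr) || nrow(tr) == 0) { notes <- c(notes, paste("trace", nm, "skipped (empty)")); next }
      wcsv(as.data.frame(tr), paste0("step_trace_", nm, ".csv"))
      fmt <- as.data.frame(tr)
      num <- vapply(fmt, is.numeric, logical(1)) & names(fmt) != "iteration" &
        names(fmt) != "n_snps"
      fmt[num] <- lapply(fmt[num], format_metric)
      p <- file.path(dir, paste0("step_trace_", nm, ".txt"))
      utils::write.table(fmt, p, sep = "\t", row.names = FALSE, quote = FALSE)
      written <- c(written, p)
    }
  } else notes <- c(notes, "stepwise stage skipped (no trace)")

  curves <- if (is.data.frame(curve)) list(model = curve) else curve
  if (length(curves)) {
    for (nm in names(curves))
      wcsv(curves[[nm]], paste0("overfitting_curve_", nm, ".csv"))
  } else notes <- c(notes, "overfitting-curve stage skipped")

  if (!is.null(scan) && nrow(scan) > 0) {
    wcsv(scan, "scan_manhattan.csv")
  } else notes <- c(notes, "single-marker scan skipped")

  if (!is.null(cm)) {
    tab <- as.data.frame.matrix(cm$table)
    tab <- cbind(observed = rownames(tab), tab)
    wcsv(tab, "confusion_matrix.csv")
  } else notes <- c(notes, "confusion matrix skipped")

  summary_path <- file.path(dir, "run_summary.txt")
  writeLines(c("mlgwas report bundle",
               paste("files:", length(written)),
               if (length(notes)) paste("note:", notes)), summary_path)
  written <- c(written, summary_path)
  invisible(written)
}
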