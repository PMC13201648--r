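#' Write simulated cohort inputs to disk
#'
#' Writes `clinical.csv`, `expr_baseline.tsv`, `expr_c2d8.tsv` and
#' `reference.tsv` (expression as genes-by-samples TSV with a `gene` column).
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_inputs <- function(sim, dir) {
  stopifnot(is.list(sim),
            all(c("clinical", "expr_baseline", "expr_c2d8", "reference") %in% names(sim)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  for (nm in c("expr_baseline", "expr_c2d8", "reference"))
    utils::write.table(sim[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write simulated chromatin inputs to disk
#'
#' Writes `peaks.bed` (BED6, 0-based half-open) with a sidecar
#' `peak_stats.tsv` (`peak_id`, `log2fc`, `fdr`), plus `motif_hits.tsv`,
#' `genes.tsv` and `trend_expr.tsv`.
#'
#' @param sim Output of [simulate_peaks_and_motifs()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_chromatin_inputs <- function(sim, dir) {
  stopifnot(is.list(sim),
            all(c("peaks", "motif_hits", "genes", "trend_expr") %in% names(sim)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bed <- data.frame(chrom = sim$peaks$chrom, start = sim$peaks$start,
                    end = sim$peaks$end, name = sim$peaks$peak_id,
                    score = 0, strand = ".")
  utils::write.table(bed, file.path(dir, "peaks.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$peaks[c("peak_id", "log2fc", "fdr")],
                     file.path(dir, "peak_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$motif_hits, file.path(dir, "motif_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$trend_expr, file.path(dir, "trend_expr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a genes-by-samples expression TSV
#'
#' Expects a header row of sample ids and a first column of gene symbols
#' (column name `gene`).
#'
#' @param path TSV file path.
#' @return Expression tibble (`gene` + numeric sample columns).
#' @export
read_expression_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene" %in% names(d)) names(d)[1] <- "gene"
  tibble::as_tibble(d)
}
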