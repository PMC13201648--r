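#' Analysis threshold registry
#'
#' A single object holds every hard cutoff used downstream, so a full run is
#' reproducible from one configuration. Defaults are the printed study
#' constants: responders are patients with PFS of at least 2 months; a variant
#' is called mutant when at least 5% of covering reads carry the mutant
#' allele; differential expression and differential peaks use |log2FC| >= 1 at
#' FDR < 0.05; copy-number calls use log2 ratio >= 1 (amplified) and <= -1
#' (loss); motif analyses evaluate at most 60,000 peaks; peak-to-gene mapping
#' uses a 3 kb window and retains genes proximal to more than one site.
#'
#' @param pfs_responder_min Months of PFS at or above which a patient is a
#'   responder. Default 2.
#' @param vaf_mutant_min Minimum variant allele fraction (inclusive) for a
#'   mutant call. Default 0.05.
#' @param min_depth Minimum read depth for a variant to count as covered;
#'   below it the variant contributes a no-call. Default 1.
#' @param de_lfc_cut Absolute log2 fold-change cutoff for differential
#'   expression / differential peaks. Default 1.
#' @param de_fdr_cut FDR cutoff for significance calls. Default 0.05.
#' @param cnv_amp_min log2 copy-ratio at or above which a gene is amplified.
#'   Default 1.
#' @param cnv_loss_max log2 copy-ratio at or below which a gene is lost.
#'   Default -1.
#' @param peak_cap Maximum number of peaks entering motif analyses; larger
#'   sets are randomly down-sampled. Default 60000.
#' @param gene_window Distance (bp) from a TSS to a peak interval within which
#'   the gene counts as proximal. Default 3000.
#' @param min_sites_per_gene Minimum number of proximal qualifying sites for a
#'   gene to be retained ("more than one site" reads as >= 2). Default 2.
#' @param nes_display_cut Absolute normalized enrichment score used when
#'   filtering GSEA results for display. Default 2.
#' @param tf_top_k Number of top transcription factors reported by
#'   [tf_enrichment()]. Default 10.
#' @param haldane Logical; report zero-cell odds ratios with a +0.5 Haldane
#'   correction instead of an infinite sentinel. Default FALSE.
#' @param rng_seed Integer seed used by operations with internal randomness
#'   (e.g. [cap_peaks()]) when no explicit seed is given. Default 1L.
#'
#' @return A `lumishift_thresholds` list.
#' @examples
#' cfg <- threshold_config(vaf_mutant_min = 0.1)
#' cfg$vaf_mutant_min
#' @export
threshold_config <- function(pfs_responder_min = 2,
                             vaf_mutant_min = 0.05,
                             min_depth = 1,
                             de_lfc_cut = 1,
                             de_fdr_cut = 0.05,
                             cnv_amp_min = 1,
                             cnv_loss_max = -1,
                             peak_cap = 60000,
                             gene_window = 3000,
                             min_sites_per_gene = 2,
                             nes_display_cut = 2,
                             tf_top_k = 10,
                             haldane = FALSE,
                             rng_seed = 1L) {
  cfg <- list(
    pfs_responder_min = pfs_responder_min,
    vaf_mutant_min = vaf_mutant_min,
    min_depth = min_depth,
    de_lfc_cut = de_lfc_cut,
    de_fdr_cut = de_fdr_cut,
    cnv_amp_min = cnv_amp_min,
    cnv_loss_max = cnv_loss_max,
    peak_cap = peak_cap,
    gene_window = gene_window,
    min_sites_per_gene = min_sites_per_gene,
    nes_display_cut = nes_display_cut,
    tf_top_k = tf_top_k,
    haldane = isTRUE(haldane),
    rng_seed = as.integer(rng_seed)
  )
  validate_thresholds(cfg)
  structure(cfg, class = "lumishift_thresholds")
}

validate_thresholds <- function(cfg) {
  stopifnot(is.list(cfg))
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (f in c("pfs_responder_min", "vaf_mutant_min", "min_depth", "de_lfc_cut",
              "de_fdr_cut", "cnv_amp_min", "cnv_loss_max", "peak_cap",
              "gene_window", "min_sites_per_gene", "nes_display_cut",
              "tf_top_k")) {
    if (!num1(cfg[[f]])) abort(paste0("threshold `", f, "` must be a single finite number"))
  }
  if (cfg$vaf_mutant_min <= 0 || cfg$vaf_mutant_min > 1)
    abort("`vaf_mutant_min` must lie in (0, 1]")
  if (cfg$peak_cap < 1) abort("`peak_cap` must be >= 1")
  if (cfg$gene_window < 0) abort("`gene_window` must be >= 0")
  if (cfg$cnv_loss_max >= cfg$cnv_amp_min)
    abort("`cnv_loss_max` must be below `cnv_amp_min`")
  invisible(cfg)
}

#' @export
print.lumishift_thresholds <- function(x, ...) {
  cat("<lumishift thresholds>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read or write a threshold configuration as YAML
#'
#' The configuration serializes to a flat YAML mapping; unknown keys are
#' rejected, missing keys fall back to defaults.
#'
#' @param path File path.
#' @param cfg A [threshold_config()] object.
#' @return `read_threshold_config()` returns a `lumishift_thresholds` object;
#'   `write_threshold_config()` returns `path` invisibly.
#' @export
read_threshold_config <- function(path) {
  vals <- yaml::read_yaml(path)
  extra <- setdiff(names(vals), names(formals(threshold_config)))
  if (length(extra) > 0)
    abort(paste0("unknown threshold keys: ", paste(extra, collapse = ", ")))
  do.call(threshold_config, vals)
}

#' @rdname read_threshold_config
#' @export
write_threshold_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "lumishift_thresholds"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
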