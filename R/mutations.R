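#' Infer mutation status from read pileups
#'
#' Gene-level mutant / NMD (no mutation detected) calls from per-variant read
#' pileups. A (sample, gene) is `mutant` iff any panel variant has positive
#' coverage and a variant allele fraction of at least `vaf_mutant_min`
#' (inclusive: "at least 5%"); `NMD` iff at least one panel variant is
#' covered and all covered variants fall below the threshold; `no-call` iff
#' every panel variant is below the coverage floor `min_depth`. Pileup rows
#' for variants outside the panel are dropped with a warning.
#'
#' @param pileups Data frame with columns `sample`, `gene`, `variant`,
#'   `depth`, `mut_reads` (one row per sample x variant).
#' @param panel Variant panel tibble (`gene`, `variant`); defaults to the
#'   built-in [variant_panel()].
#' @param cfg [threshold_config()].
#' @return Tibble with one row per sample x panel gene: `sample`, `gene`,
#'   `status` (factor mutant/NMD/no-call), `max_vaf` (NA when uncovered),
#'   `n_covered`.
#' @examples
#' pu <- tibble::tibble(sample = "s1", gene = "ESR1", variant = "ESR1:Y537S",
#'                      depth = 1000, mut_reads = 50)
#' infer_mutation_status(pu)
#' @export
infer_mutation_status <- function(pileups, panel = variant_panel(),
                                  cfg = threshold_config()) {
  stopifnot(is.data.frame(pileups), is.data.frame(panel))
  validate_thresholds(cfg)
  need <- c("sample", "gene", "variant", "depth", "mut_reads")
  miss <- setdiff(need, names(pileups))
  if (length(miss) > 0)
    abort(paste0("`pileups` missing columns: ", paste(miss, collapse = ", ")))
  if (any(pileups$depth < 0) || any(pileups$mut_reads < 0) ||
      any(pileups$mut_reads > pileups$depth))
    abort("require 0 <= mut_reads <= depth")
  unknown <- setdiff(unique(pileups$variant), panel$variant)
  if (length(unknown) > 0) {
    warn(paste0(length(unknown), " variant(s) not in panel excluded: ",
                paste(utils::head(unknown, 5), collapse = ", ")))
    pileups <- dplyr::filter(pileups, .data$variant %in% panel$variant)
  }
  pileups |>
    dplyr::mutate(
      covered = .data$depth >= cfg$min_depth & .data$depth > 0,
      vaf = ifelse(.data$depth > 0, .data$mut_reads / .data$depth, NA_real_)
    ) |>
    dplyr::group_by(.data$sample, .data$gene) |>
    dplyr::summarise(
      n_covered = sum(.data$covered),
      max_vaf = if (any(.data$covered)) max(.data$vaf[.data$covered]) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      status = factor(
        dplyr::case_when(
          n_covered == 0 ~ "no-call",
          max_vaf >= cfg$vaf_mutant_min ~ "mutant",
          TRUE ~ "NMD"
        ),
        levels = c("mutant", "NMD", "no-call")
      )
    ) |>
    dplyr::select("sample", "gene", "status", "max_vaf", "n_covered")
}

#' Classify copy-number calls from log2 ratios
#'
#' A gene is `amplified` iff its log2 copy-number ratio (e.g. resistant vs
#' parental) is at least `cnv_amp_min`, `loss` iff at most `cnv_loss_max`,
#' `neutral` otherwise. Both boundary comparisons are inclusive.
#'
#' @param data Data frame with columns `gene` and `log2_ratio` (finite).
#' @param cfg [threshold_config()].
#' @return `data` with an added factor column `cnv_class`
#'   (amplified/neutral/loss).
#' @examples
#' classify_cnv(tibble::tibble(gene = c("A", "B"), log2_ratio = c(1, -1.5)))
#' @export
classify_cnv <- function(data, cfg = threshold_config()) {
  stopifnot(is.data.frame(data))
  validate_thresholds(cfg)
  if (!all(c("gene", "log2_ratio") %in% names(data)))
    abort("`data` must have columns `gene` and `log2_ratio`")
  if (any(!is.finite(data$log2_ratio))) abort("`log2_ratio` must be finite")
  dplyr::mutate(data, cnv_class = factor(
    dplyr::case_when(
      .data$log2_ratio >= cfg$cnv_amp_min ~ "amplified",
      .data$log2_ratio <= cfg$cnv_loss_max ~ "loss",
      TRUE ~ "neutral"
    ),
    levels = c("amplified", "neutral", "loss")
  ))
}

#' Restrict calls to a cancer gene list
#'
#' Keeps only rows whose `gene` appears in a user-supplied cancer gene list
#' (e.g. an OncoKB export; no list is bundled). Matching is case-insensitive
#' after whitespace stripping.
#'
#' @param data Data frame with a `gene` column.
#' @param cancer_genes Character vector of gene symbols.
#' @return Filtered tibble; attribute `n_retained` records the row count, and
#'   a message reports it.
#' @export
filter_cancer_genes <- function(data, cancer_genes) {
  stopifnot(is.data.frame(data), "gene" %in% names(data))
  if (!is.character(cancer_genes)) abort("`cancer_genes` must be a character vector")
  out <- dplyr::filter(data, gene_key(.data$gene) %in% gene_key(cancer_genes))
  inform(paste0(nrow(out), " of ", nrow(data), " gene record(s) retained"))
  attr(out, "n_retained") <- nrow(out)
  out
}
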