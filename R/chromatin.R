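#' Classify differential chromatin peaks
#'
#' Partitions peaks into `up` (log2FC >= `de_lfc_cut` and FDR <
#' `de_fdr_cut`), `down` (log2FC <= -`de_lfc_cut`, same FDR cut),
#' `unchanged` (-`de_lfc_cut` < log2FC < `de_lfc_cut` with FDR < 1 — i.e.
#' effectively any FDR, matching the reference-set definition used for motif
#' analyses), and `excluded` (everything else, e.g. a large fold change that
#' fails the FDR cut). The partition is exhaustive and mutually exclusive.
#'
#' @param peaks Data frame with numeric columns `log2fc` and `fdr` (finite).
#' @param cfg [threshold_config()].
#' @return `peaks` with an added factor column `peak_class`; attribute
#'   `class_counts` holds the per-class tally.
#' @examples
#' classify_differential_peaks(
#'   tibble::tibble(log2fc = c(1.5, 0, 1.5), fdr = c(0.01, 0.99, 0.2)))
#' @export
classify_differential_peaks <- function(peaks, cfg = threshold_config()) {
  stopifnot(is.data.frame(peaks))
  validate_thresholds(cfg)
  if (!all(c("log2fc", "fdr") %in% names(peaks)))
    abort("`peaks` must have columns `log2fc` and `fdr`")
  if (any(!is.finite(peaks$log2fc)) || any(!is.finite(peaks$fdr)))
    abort("peak statistics must be finite")
  lfc <- peaks$log2fc; fdr <- peaks$fdr
  out <- dplyr::mutate(peaks, peak_class = factor(
    dplyr::case_when(
      lfc >= cfg$de_lfc_cut & fdr < cfg$de_fdr_cut ~ "up",
      lfc <= -cfg$de_lfc_cut & fdr < cfg$de_fdr_cut ~ "down",
      lfc > -cfg$de_lfc_cut & lfc < cfg$de_lfc_cut & fdr < 1 ~ "unchanged",
      TRUE ~ "excluded"
    ),
    levels = c("up", "down", "unchanged", "excluded")
  ))
  attr(out, "class_counts") <- table(out$peak_class)
  out
}

#' Cap a peak set for motif analysis
#'
#' Motif analyses evaluate at most `peak_cap` peaks (60,000 by default); a
#' larger set is reduced to exactly the cap by uniform random sampling
#' without replacement, preserving the original row order. Smaller sets pass
#' through unchanged.
#'
#' @param peaks Data frame of peaks.
#' @param cfg [threshold_config()].
#' @param seed Integer seed for the sampling; defaults to `cfg$rng_seed`.
#' @return A tibble with `min(nrow(peaks), peak_cap)` rows.
#' @export
cap_peaks <- function(peaks, cfg = threshold_config(), seed = cfg$rng_seed) {
  stopifnot(is.data.frame(peaks))
  validate_thresholds(cfg)
  if (nrow(peaks) <= cfg$peak_cap) return(tibble::as_tibble(peaks))
  keep <- withr::with_seed(as.integer(seed),
                           sort(sample.int(nrow(peaks), cfg$peak_cap)))
  tibble::as_tibble(peaks[keep, , drop = FALSE])
}

check_hits <- function(hits) {
  stopifnot(is.data.frame(hits), "peak_id" %in% names(hits))
  motifs <- setdiff(names(hits), "peak_id")
  if (length(motifs) == 0) abort("`hits` has no motif columns")
  for (m in motifs) {
    v <- hits[[m]]
    if (!(is.logical(v) || all(v %in% c(0, 1))))
      abort(paste0("motif column `", m, "` must be logical or 0/1"))
  }
  if (anyDuplicated(hits$peak_id)) abort("`hits` has duplicated peak ids")
  motifs
}

#' Motif enrichment between two peak sets
#'
#' For each motif, computes the percentage of foreground peaks containing it
#' (%TP), the percentage of background peaks containing it (%FP), the
#' enrichment score `%TP - %FP` (bounded in \[-100, 100\]), a one-sided
#' Fisher's exact p-value on the foreground/background x motif/no-motif
#' table, and FDR across motifs.
#'
#' @param hits Wide motif-hit table: a `peak_id` column plus one logical
#'   (or 0/1) column per motif.
#' @param fg,bg Character vectors of foreground and background peak ids;
#'   non-empty, disjoint, all present in `hits`.
#' @param cfg [threshold_config()].
#' @return Tibble: `motif`, `pct_tp`, `pct_fp`, `score`, `odds_ratio`,
#'   `p_value`, `fdr`.
#' @export
motif_enrichment <- function(hits, fg, bg, cfg = threshold_config()) {
  validate_thresholds(cfg)
  motifs <- check_hits(hits)
  if (length(fg) == 0 || length(bg) == 0) abort("`fg` and `bg` must be non-empty")
  if (length(intersect(fg, bg)) > 0) abort("`fg` and `bg` must be disjoint")
  missing <- setdiff(c(fg, bg), hits$peak_id)
  if (length(missing) > 0)
    abort(paste0(length(missing), " peak id(s) absent from `hits`"))
  fgm <- hits[match(fg, hits$peak_id), motifs, drop = FALSE]
  bgm <- hits[match(bg, hits$peak_id), motifs, drop = FALSE]
  tp <- unname(vapply(fgm, function(v) sum(as.logical(v)), numeric(1)))
  fp <- unname(vapply(bgm, function(v) sum(as.logical(v)), numeric(1)))
  ft <- fisher_exact_one_sided(
    a = tp, b = length(fg) - tp, c = fp, d = length(bg) - fp,
    haldane = cfg$haldane
  )
  res <- tibble::tibble(
    motif = motifs,
    pct_tp = 100 * tp / length(fg),
    pct_fp = 100 * fp / length(bg),
    odds_ratio = ft$odds_ratio,
    p_value = ft$p_value
  )
  res$score <- res$pct_tp - res$pct_fp
  res$fdr <- bh_fdr(res$p_value)
  res[c("motif", "pct_tp", "pct_fp", "score", "odds_ratio", "p_value", "fdr")]
}

#' Motif co-occurrence partition
#'
#' Restricted to peaks carrying motif A and/or motif B, partitions them into
#' the mutually exclusive categories `a_only`, `b_only` and `both`; the three
#' fractions sum to 1. This is the statistic behind statements like "70% of
#' repressed sites contained an ERalpha motif without a co-occurring FOXA1
#' motif".
#'
#' @param hits Wide motif-hit table (see [motif_enrichment()]).
#' @param motif_a,motif_b Motif column names.
#' @param peaks Optional character vector of peak ids restricting the
#'   analysis (e.g. one differential class).
#' @return Tibble: `category`, `n`, `fraction`; attribute `n_total` is the
#'   size of the restriction set.
#' @export
motif_cooccurrence_partition <- function(hits, motif_a, motif_b, peaks = NULL) {
  motifs <- check_hits(hits)
  for (m in c(motif_a, motif_b))
    if (!m %in% motifs) abort(paste0("motif `", m, "` not found in `hits`"))
  if (!is.null(peaks)) hits <- hits[hits$peak_id %in% peaks, , drop = FALSE]
  a <- as.logical(hits[[motif_a]]); b <- as.logical(hits[[motif_b]])
  keep <- a | b
  if (!any(keep)) abort("no peak carries either motif in the restriction set")
  a <- a[keep]; b <- b[keep]
  n <- c(a_only = sum(a & !b), b_only = sum(!a & b), both = sum(a & b))
  out <- tibble::tibble(category = factor(names(n), levels = names(n)),
                        n = as.integer(n), fraction = as.numeric(n / sum(n)))
  attr(out, "n_total") <- sum(n)
  out
}

#' Map peaks to proximal genes
#'
#' A gene is proximal to a peak iff the distance from its TSS to the peak
#' interval is at most `gene_window` (0 if the TSS lies inside the peak;
#' coordinates are BED-convention 0-based half-open and strand is ignored).
#' A gene qualifies when it is proximal to at least `min_sites_per_gene`
#' peaks ("more than one site" at the default of 2).
#'
#' @param peaks Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open, `start < end`) and `peak_id`.
#' @param genes Data frame with columns `gene`, `chrom`, `tss` (bp, >= 0).
#' @param cfg [threshold_config()].
#' @return Tibble: `gene`, `chrom`, `tss`, `n_sites` (proximal peak count),
#'   `retained` (n_sites >= `min_sites_per_gene`).
#' @export
map_peaks_to_genes <- function(peaks, genes, cfg = threshold_config()) {
  validate_thresholds(cfg)
  stopifnot(is.data.frame(peaks), is.data.frame(genes))
  if (!all(c("chrom", "start", "end") %in% names(peaks)))
    abort("`peaks` must have columns chrom, start, end")
  if (!all(c("gene", "chrom", "tss") %in% names(genes)))
    abort("`genes` must have columns gene, chrom, tss")
  if (any(peaks$start >= peaks$end)) abort("peak intervals require start < end")
  if (any(genes$tss < 0)) abort("TSS positions must be >= 0")
  shared <- intersect(unique(peaks$chrom), unique(genes$chrom))
  if (length(shared) == 0) {
    abort(paste0(
      "no shared chromosome names between `peaks` and `genes`; peaks use: ",
      paste(utils::head(unique(peaks$chrom), 5), collapse = ", "),
      " — genes use: ",
      paste(utils::head(unique(genes$chrom), 5), collapse = ", ")
    ))
  }
  w <- cfg$gene_window
  counts <- integer(nrow(genes))
  for (ch in shared) {
    pi <- which(peaks$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (length(pi) == 0 || length(gi) == 0) next
    # TSS within distance w of [start, end) iff start - w <= tss <= end - 1 + w
    win <- IRanges::IRanges(start = peaks$start[pi] - w,
                            end = peaks$end[pi] - 1 + w)
    tsspt <- IRanges::IRanges(start = genes$tss[gi], width = 1)
    counts[gi] <- IRanges::countOverlaps(tsspt, win)
  }
  tibble::tibble(gene = genes$gene, chrom = genes$chrom, tss = genes$tss,
                 n_sites = counts,
                 retained = counts >= cfg$min_sites_per_gene)
}

#' Expression trend test across treatment conditions
#'
#' For each gene set (e.g. genes proximal to sites where FOXA1 co-occurs
#' with MEF2, TEAD or STAT motifs) and each pair of conditions, tests whether
#' gene expression shifts between conditions using a paired two-sided
#' Wilcoxon signed-rank test across the genes of the set (each gene is its
#' own pair). Set `paired = FALSE` for the unpaired Mann-Whitney fallback.
#'
#' @param gene_sets Named list of gene-symbol vectors.
#' @param expr Data frame with a `gene` column and one numeric column per
#'   condition; every set gene must be present.
#' @param conditions Character vector (length >= 2) of condition column
#'   names, in time-course order; all ordered pairs are tested.
#' @param paired Use the paired signed-rank test (default) or the unpaired
#'   rank-sum test.
#' @return Tibble: `set`, `comparison`, `n_genes`, `statistic`, `p_value`,
#'   `median_diff` (second condition minus first).
#' @export
expression_trend_test <- function(gene_sets, expr,
                                  conditions = c("parental", "m2", "resistant"),
                                  paired = TRUE) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)),
            is.data.frame(expr), "gene" %in% names(expr))
  if (length(conditions) < 2) abort("need at least two conditions")
  miss <- setdiff(conditions, names(expr))
  if (length(miss) > 0)
    abort(paste0("condition column(s) missing from `expr`: ",
                 paste(miss, collapse = ", ")))
  pairs_idx <- utils::combn(length(conditions), 2)
  purrr::imap(gene_sets, function(gs, nm) {
    idx <- match(gene_key(gs), gene_key(expr$gene))
    if (any(is.na(idx)))
      abort(paste0("set `", nm, "` has genes absent from `expr`"))
    purrr::map(seq_len(ncol(pairs_idx)), function(k) {
      c1 <- conditions[pairs_idx[1, k]]; c2 <- conditions[pairs_idx[2, k]]
      x <- expr[[c1]][idx]; y <- expr[[c2]][idx]
      tst <- if (paired) wilcoxon_paired_two_sided(x, y)
             else mann_whitney_two_sided(x, y)
      tibble::tibble(set = nm, comparison = paste(c1, "vs", c2),
                     n_genes = length(idx),
                     statistic = tst$statistic, p_value = tst$p_value,
                     median_diff = median(y - x))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}
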