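#' @noRd
#' Expression tables are tibbles with a `gene` character column followed by
#' one numeric column per sample.
as_expr_matrix <- function(expr, arg = "expr") {
  if (!is.data.frame(expr)) abort(paste0("`", arg, "` must be a data frame"))
  if (!"gene" %in% names(expr))
    abort(paste0("`", arg, "` must have a `gene` column"))
  g <- trimws(as.character(expr$gene))
  if (anyDuplicated(toupper(g)))
    abort(paste0("`", arg, "` has duplicated gene symbols"))
  m <- as.matrix(expr[setdiff(names(expr), "gene")])
  if (!is.numeric(m) || ncol(m) == 0)
    abort(paste0("`", arg, "` must have numeric sample columns"))
  rownames(m) <- g
  m
}

gene_key <- function(x) toupper(trimws(x))

#' z-normalize expression against a reference cohort
#'
#' Per gene, expression is centered and scaled by the gene's mean and standard
#' deviation in an independent reference cohort (the study design uses 138
#' ER+ breast cancer cases), so scores are comparable across samples and
#' cohorts. Genes absent from either table are dropped; reference genes with
#' zero variance are dropped with a warning. Gene symbols are matched
#' case-insensitively after whitespace stripping.
#'
#' @param expr Expression tibble (`gene` column + one numeric column per
#'   sample), log-scale normalized values.
#' @param reference Reference-cohort expression tibble, same layout, at least
#'   2 samples.
#' @return A z-score tibble with the same layout as `expr`, restricted to the
#'   usable gene intersection. Attributes: `n_shared` (intersection size
#'   before the sd filter) and `dropped_constant` (genes removed for zero
#'   reference sd).
#' @examples
#' expr <- tibble::tibble(gene = c("ESR1", "PGR"), s1 = c(8, 5), s2 = c(6, 7))
#' ref <- tibble::tibble(gene = c("ESR1", "PGR"),
#'                       r1 = c(7, 6), r2 = c(5, 4), r3 = c(6, 5))
#' zscore_to_reference(expr, ref)
#' @export
zscore_to_reference <- function(expr, reference) {
  em <- as_expr_matrix(expr, "expr")
  rm_ <- as_expr_matrix(reference, "reference")
  if (ncol(rm_) < 2) abort("`reference` must have at least 2 samples")
  shared <- intersect(gene_key(rownames(em)), gene_key(rownames(rm_)))
  if (length(shared) == 0) abort("no genes shared between `expr` and `reference`")
  em <- em[match(shared, gene_key(rownames(em))), , drop = FALSE]
  rm_ <- rm_[match(shared, gene_key(rownames(rm_))), , drop = FALSE]
  mu <- rowMeans(rm_)
  sdv <- apply(rm_, 1, sd)
  keep <- sdv > 0
  dropped <- rownames(em)[!keep]
  if (length(dropped) > 0)
    warn(paste0(length(dropped), " gene(s) with zero reference variance dropped: ",
                paste(utils::head(dropped, 5), collapse = ", "),
                if (length(dropped) > 5) ", ..." else ""))
  z <- (em[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  out <- tibble::as_tibble(z)
  out <- dplyr::bind_cols(tibble::tibble(gene = rownames(em)[keep]), out)
  attr(out, "n_shared") <- length(shared)
  attr(out, "dropped_constant") <- dropped
  out
}

#' Score one gene signature
#'
#' A sample's signature score is the unweighted mean of its z-scores over the
#' signature genes present in the matrix; signature genes missing from the
#' matrix are skipped and counted.
#'
#' @param z z-score tibble from [zscore_to_reference()].
#' @param genes Character vector of signature gene symbols.
#' @param name Signature name used in the output.
#' @return Tibble with columns `sample`, `signature`, `score`, `n_genes_used`.
#'   Attribute `missing_genes` lists signature genes absent from `z`.
#' @export
score_signature <- function(z, genes, name = "signature") {
  zm <- as_expr_matrix(z, "z")
  stopifnot(is.character(genes), length(genes) > 0)
  if (anyDuplicated(gene_key(genes))) abort("signature genes must be unique")
  hit <- match(gene_key(genes), gene_key(rownames(zm)))
  present <- !is.na(hit)
  if (!any(present)) abort(paste0("no genes of signature `", name, "` present in `z`"))
  sub <- zm[hit[present], , drop = FALSE]
  out <- tibble::tibble(
    sample = colnames(zm),
    signature = name,
    score = unname(colMeans(sub)),
    n_genes_used = sum(present)
  )
  attr(out, "missing_genes") <- genes[!present]
  out
}

#' Score all built-in signatures
#'
#' Applies [score_signature()] to each signature and returns one row per
#' sample with one column per signature.
#'
#' @param z z-score tibble from [zscore_to_reference()].
#' @param signatures Named list of gene vectors; defaults to
#'   [breast_signatures()].
#' @return Wide tibble: `sample` plus one numeric score column per signature.
#' @export
score_signatures <- function(z, signatures = breast_signatures()) {
  stopifnot(is.list(signatures), !is.null(names(signatures)))
  long <- purrr::imap(signatures, function(g, nm) score_signature(z, g, nm)) |>
    purrr::list_rbind()
  tidyr::pivot_wider(long[c("sample", "signature", "score")],
                     names_from = "signature", values_from = "score")
}

#' ERalpha activity score
#'
#' Mean z-score over the 21 estrogen-induced genes — the proxy for ERalpha
#' pathway dependence. The estrogen-repressed panel is scored separately via
#' [score_signature()] and is never subtracted.
#'
#' @inheritParams score_signature
#' @return As [score_signature()], with `signature = "era_induced"`.
#' @export
era_activity <- function(z) {
  score_signature(z, breast_signatures()$era_induced, "era_induced")
}

#' Classify tumors as Lum-high or Lum-low
#'
#' A sample is Lum-high iff it is strictly above the cohort median on both the
#' ERalpha activity score and the luminal TF score; median-tied samples are
#' Lum-low. Medians are computed over the supplied sample set (typically all
#' baseline biopsies).
#'
#' @param scores Wide tibble with a `sample` column and the two score columns.
#' @param era,lumtf Column names (strings) of the ERalpha activity and luminal
#'   TF scores. Defaults match [score_signatures()] output.
#' @return `scores` with an added factor column `lum_class` (levels
#'   `Lum-high`, `Lum-low`); attribute `medians` holds the two cutoffs.
#' @examples
#' sc <- tibble::tibble(sample = letters[1:4],
#'                      era_induced = c(0.5, -0.2, 0.8, -0.9),
#'                      luminal_tf = c(0.4, -0.1, 0.9, -0.7))
#' classify_luminal(sc)
#' @export
classify_luminal <- function(scores, era = "era_induced", lumtf = "luminal_tf") {
  stopifnot(is.data.frame(scores), "sample" %in% names(scores))
  for (cl in c(era, lumtf)) {
    if (!cl %in% names(scores)) abort(paste0("column `", cl, "` not found in `scores`"))
    if (!is.numeric(scores[[cl]])) abort(paste0("column `", cl, "` must be numeric"))
  }
  if (nrow(scores) < 2) abort("need at least 2 samples to classify")
  if (any(!is.finite(scores[[era]])) || any(!is.finite(scores[[lumtf]])))
    abort("scores must be finite")
  med_era <- median(scores[[era]])
  med_lum <- median(scores[[lumtf]])
  hi <- scores[[era]] > med_era & scores[[lumtf]] > med_lum
  out <- dplyr::mutate(
    scores,
    lum_class = factor(ifelse(hi, "Lum-high", "Lum-low"),
                       levels = c("Lum-high", "Lum-low"))
  )
  attr(out, "medians") <- c(era = med_era, lumtf = med_lum)
  out
}
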