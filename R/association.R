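#' Paired differential expression
#'
#' Per-gene paired comparison of on-treatment vs baseline log2 expression.
#' The log2 fold change is the mean within-pair difference and the p-value
#' comes from an ordinary paired t-statistic (a deliberate, documented
#' simplification relative to moderated-variance pipelines); FDR via
#' [bh_fdr()]. Genes are flagged significant at `|log2FC| >= de_lfc_cut` and
#' `fdr < de_fdr_cut`.
#'
#' @param base,treated Expression tibbles (`gene` + sample columns) on the
#'   log2 scale.
#' @param pairs Data frame with columns `base` and `treated` naming the
#'   paired sample columns; at least 3 pairs.
#' @param cfg [threshold_config()].
#' @return Tibble: `gene`, `log2fc`, `statistic`, `p_value`, `fdr`,
#'   `significant`.
#' @export
differential_expression_paired <- function(base, treated, pairs,
                                           cfg = threshold_config()) {
  validate_thresholds(cfg)
  bm <- as_expr_matrix(base, "base")
  tm <- as_expr_matrix(treated, "treated")
  stopifnot(is.data.frame(pairs), all(c("base", "treated") %in% names(pairs)))
  if (nrow(pairs) < 3) abort("need at least 3 pairs")
  miss_b <- setdiff(pairs$base, colnames(bm))
  miss_t <- setdiff(pairs$treated, colnames(tm))
  if (length(miss_b) > 0 || length(miss_t) > 0)
    abort(paste0("unpaired samples; missing mates: ",
                 paste(c(miss_b, miss_t), collapse = ", ")))
  shared <- intersect(rownames(bm), rownames(tm))
  if (length(shared) == 0) abort("no shared genes")
  d <- tm[shared, pairs$treated, drop = FALSE] - bm[shared, pairs$base, drop = FALSE]
  n <- ncol(d)
  lfc <- rowMeans(d)
  sdd <- apply(d, 1, sd)
  tstat <- ifelse(sdd > 0, lfc / (sdd / sqrt(n)), ifelse(lfc == 0, 0, Inf * sign(lfc)))
  p <- ifelse(is.finite(tstat), 2 * stats::pt(-abs(tstat), df = n - 1),
              ifelse(lfc == 0, 1, 0))
  p[sdd == 0 & lfc == 0] <- 1
  fdr <- unname(bh_fdr(p))
  tibble::tibble(gene = shared, log2fc = unname(lfc), statistic = unname(tstat),
                 p_value = unname(p), fdr = fdr,
                 significant = abs(lfc) >= cfg$de_lfc_cut & fdr < cfg$de_fdr_cut)
}

# Weighted running-sum enrichment score from hit positions in a ranked list.
# positions: 1-based positions of the set's genes (sorted ascending);
# w: |metric| at those positions (ignored when weighted = FALSE);
# n: universe size. The extremum of the running sum occurs at a hit point
# (just after a hit for the maximum, just before for the minimum), so only
# hit positions need evaluating.
running_sum_es <- function(positions, w, n) {
  m <- length(positions)
  wsum <- sum(w)
  if (wsum <= 0) w <- rep(1, m) # degenerate all-zero metric: fall back to unit
  wsum <- sum(w)
  step <- 1 / (n - m)
  cw <- cumsum(w) / wsum
  gap <- (positions - seq_len(m)) * step
  s_after <- cw - gap
  s_before <- c(0, cw[-m]) - gap
  hi <- max(s_after)
  lo <- min(s_before)
  if (hi >= -lo) hi else lo
}

#' Preranked gene-set enrichment
#'
#' Classic weighted Kolmogorov-Smirnov-style enrichment on a ranked gene
#' list: walking down the ranking, set members increment a running sum in
#' proportion to the magnitude of their metric and non-members decrement it
#' uniformly; the enrichment score (ES) is the signed extremum. The
#' normalized score (NES) divides ES by the mean |ES| of gene-label
#' permutations of matching sign, and the two-sided p-value is the
#' sign-matched permutation tail, doubled and capped at 1. FDR via
#' [bh_fdr()] across sets.
#'
#' @param ranked Data frame with columns `gene` and `metric` (finite; e.g. a
#'   DE t-statistic). Ties keep input order.
#' @param sets Named list of gene-symbol vectors; a set whose overlap with
#'   the ranking is below 2 is skipped with a warning.
#' @param n_perm Number of gene-label permutations per set.
#' @param seed Integer seed for the permutations.
#' @param weighted If FALSE, hit increments are uniform (unit weights).
#' @return Tibble: `set`, `size`, `es`, `nes`, `p_value`, `fdr`,
#'   `leading_edge` (list-column of genes up to the ES extremum).
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, seed = 1L,
                           weighted = TRUE) {
  stopifnot(is.data.frame(ranked), all(c("gene", "metric") %in% names(ranked)))
  if (any(!is.finite(ranked$metric))) abort("`metric` must be finite")
  stopifnot(is.list(sets), !is.null(names(sets)), n_perm >= 1)
  ord <- order(ranked$metric, decreasing = TRUE)
  genes <- gene_key(ranked$gene[ord])
  metric <- ranked$metric[ord]
  n <- length(genes)
  absw <- abs(metric)

  res <- withr::with_seed(as.integer(seed), {
    purrr::imap(sets, function(set_genes, nm) {
      pos <- sort(which(genes %in% gene_key(set_genes)))
      m <- length(pos)
      if (m < 2 || m >= n) {
        warn(paste0("set `", nm, "` skipped (overlap with universe: ", m, ")"))
        return(NULL)
      }
      w <- if (weighted) absw[pos] else rep(1, m)
      es <- running_sum_es(pos, w, n)
      perm <- vapply(seq_len(n_perm), function(i) {
        pp <- sort(sample.int(n, m))
        running_sum_es(pp, if (weighted) absw[pp] else rep(1, m), n)
      }, numeric(1))
      same <- perm[sign(perm) == sign(es)]
      nes <- if (length(same) > 0) es / mean(abs(same)) else NA_real_
      p <- min(1, 2 * (1 + sum(abs(same) >= abs(es))) / (1 + length(same)))
      # leading edge: hits at or before the extremum of the running sum
      le_pos <- if (es >= 0) {
        cw <- cumsum(w) / sum(w)
        gap <- (pos - seq_len(m)) / (n - m)
        pos[seq_len(which.max(cw - gap))]
      } else {
        cw0 <- c(0, cumsum(w)[-m] / sum(w))
        gap <- (pos - seq_len(m)) / (n - m)
        pos[which.min(cw0 - gap):m]
      }
      tibble::tibble(set = nm, size = m, es = es, nes = nes, p_value = p,
                     leading_edge = list(ranked$gene[ord][le_pos]))
    }) |> purrr::list_rbind()
  })
  if (nrow(res) == 0) return(res)
  res$fdr <- bh_fdr(res$p_value)
  res[c("set", "size", "es", "nes", "p_value", "fdr", "leading_edge")]
}

#' Per-gene association with response, adjusted for covariates
#'
#' Fits, for every gene, a logistic regression of response class on
#' standardized expression plus clinical covariates (treatment arm, PAM50
#' subtype, ...). The coefficient is reported in log2-odds units per standard
#' deviation of expression, with a two-sided Wald p-value; positive values
#' are Resp-enriched. Genes with complete separation are flagged and given
#' sentinel (`NA`) estimates instead of divergent ones.
#'
#' @param expr Expression tibble (`gene` + sample columns).
#' @param sample_data Data frame with one row per sample: a `sample` column,
#'   the `response` column (values NR/Resp) and the covariate columns.
#' @param covariates Character vector of covariate column names in
#'   `sample_data` (may be empty).
#' @param cfg [threshold_config()].
#' @return Tibble: `gene`, `log2_odds`, `p_value`, `fdr`, `separated`,
#'   `group` (NR-enriched / Resp-enriched / none at `de_fdr_cut`).
#' @export
response_gene_association <- function(expr, sample_data,
                                      covariates = character(),
                                      cfg = threshold_config()) {
  validate_thresholds(cfg)
  em <- as_expr_matrix(expr, "expr")
  stopifnot(is.data.frame(sample_data),
            all(c("sample", "response") %in% names(sample_data)))
  miss <- setdiff(covariates, names(sample_data))
  if (length(miss) > 0)
    abort(paste0("covariates not in `sample_data`: ", paste(miss, collapse = ", ")))
  sample_data <- dplyr::filter(sample_data, .data$response %in% c("NR", "Resp"))
  idx <- match(sample_data$sample, colnames(em))
  if (any(is.na(idx))) abort("`sample_data` contains samples absent from `expr`")
  em <- em[, idx, drop = FALSE]
  y <- as.integer(sample_data$response == "Resp")
  if (length(unique(y)) < 2) abort("both response classes must be present")
  if (length(y) < 10) abort("need at least 10 samples")
  covm <- if (length(covariates) > 0) {
    stats::model.matrix(~ ., data = sample_data[covariates])[, -1, drop = FALSE]
  } else {
    matrix(numeric(0), nrow = length(y), ncol = 0)
  }
  fit_one <- function(x) {
    s <- sd(x)
    if (s == 0) return(c(NA_real_, NA_real_, 1)) # constant gene: separated sentinel
    xs <- (x - mean(x)) / s
    X <- cbind(xs = xs, covm)
    sep_warn <- FALSE
    fit <- withCallingHandlers(
      glm(y ~ X, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
    beta <- coef(fit)["Xxs"]
    se <- sqrt(diag(stats::vcov(fit)))["Xxs"]
    if (is.na(beta) || (sep_warn && abs(beta) > 8))
      return(c(NA_real_, NA_real_, 1))
    z <- beta / se
    c(beta / log(2), 2 * pnorm(-abs(z)), 0)
  }
  out <- t(apply(em, 1, fit_one))
  res <- tibble::tibble(
    gene = rownames(em),
    log2_odds = out[, 1],
    p_value = out[, 2],
    separated = out[, 3] == 1
  )
  res$fdr <- bh_fdr(res$p_value)
  res$group <- factor(
    dplyr::case_when(
      is.na(res$fdr) ~ "none",
      res$fdr < cfg$de_fdr_cut & res$log2_odds > 0 ~ "Resp-enriched",
      res$fdr < cfg$de_fdr_cut & res$log2_odds < 0 ~ "NR-enriched",
      TRUE ~ "none"
    ),
    levels = c("NR-enriched", "Resp-enriched", "none")
  )
  res[c("gene", "log2_odds", "p_value", "fdr", "separated", "group")]
}

#' Transcription-factor target enrichment
#'
#' For each transcription factor in a user-supplied TF-to-target library,
#' tests over-representation of its targets in a query gene list against a
#' gene universe via a one-sided Fisher's exact test; FDR across TFs via
#' [bh_fdr()]. The `top_hit` column marks the `tf_top_k` factors with the
#' largest odds ratios among those at `fdr < de_fdr_cut`.
#'
#' @param query Character vector of query genes (must lie in `universe`).
#' @param library Data frame with columns `tf` and `target` (long form).
#' @param universe Character vector of all evaluable genes.
#' @param cfg [threshold_config()].
#' @return Tibble, one row per TF: `tf`, `n_targets`, `n_overlap`,
#'   `odds_ratio`, `p_value`, `fdr`, `top_hit`, `overlap_genes`
#'   (list-column), sorted by decreasing odds ratio.
#' @export
tf_enrichment <- function(query, library, universe, cfg = threshold_config()) {
  validate_thresholds(cfg)
  stopifnot(is.character(query), is.character(universe),
            is.data.frame(library), all(c("tf", "target") %in% names(library)))
  if (nrow(library) == 0) abort("`library` is empty")
  universe <- unique(gene_key(universe))
  query <- unique(gene_key(query))
  if (!all(query %in% universe)) abort("`query` must be a subset of `universe`")
  lib <- dplyr::mutate(library, tf = as.character(.data$tf),
                       target = gene_key(.data$target)) |>
    dplyr::filter(.data$target %in% universe) |>
    dplyr::distinct(.data$tf, .data$target)
  nq <- length(query); nu <- length(universe)
  res <- lib |>
    dplyr::group_by(.data$tf) |>
    dplyr::summarise(
      n_targets = dplyr::n(),
      n_overlap = sum(.data$target %in% query),
      overlap_genes = list(intersect(.data$target, query)),
      .groups = "drop"
    )
  ft <- fisher_exact_one_sided(
    a = res$n_overlap,
    b = nq - res$n_overlap,
    c = res$n_targets - res$n_overlap,
    d = nu - nq - (res$n_targets - res$n_overlap),
    haldane = cfg$haldane
  )
  res$odds_ratio <- ft$odds_ratio
  res$p_value <- ft$p_value
  res$fdr <- bh_fdr(res$p_value)
  res <- dplyr::arrange(res, dplyr::desc(.data$odds_ratio), .data$p_value)
  eligible <- which(res$fdr < cfg$de_fdr_cut)
  res$top_hit <- FALSE
  res$top_hit[utils::head(eligible, cfg$tf_top_k)] <- TRUE
  res[c("tf", "n_targets", "n_overlap", "odds_ratio", "p_value", "fdr",
        "top_hit", "overlap_genes")]
}
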