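#' One-sided Fisher's exact test for enrichment
#'
#' Tests over-representation in a 2x2 table with rows = in/out of the query
#' set and columns = with/without the reference property. The p-value is the
#' upper hypergeometric tail P(X >= a) at the table's margins; the odds ratio
#' is the sample (cross-product) odds ratio (a d)/(b c), not the conditional
#' MLE.
#'
#' @param a,b,c,d Non-negative counts; vectors are recycled to a common
#'   length, one test per element.
#' @param haldane If TRUE, zero-cell odds ratios use a +0.5 correction on all
#'   cells; otherwise a table with b c = 0 and a d > 0 reports `Inf` (and 0
#'   for the mirror case).
#' @return A tibble with columns `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`.
#' @examples
#' fisher_exact_one_sided(8, 2, 2, 8)
#' @export
fisher_exact_one_sided <- function(a, b, c, d, haldane = FALSE) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- unname(rep_len(as.numeric(a), n)); b <- unname(rep_len(as.numeric(b), n))
  c <- unname(rep_len(as.numeric(c), n)); d <- unname(rep_len(as.numeric(d), n))
  counts <- cbind(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0))
    abort("all counts must be finite and non-negative")
  if (any(counts != round(counts)))
    abort("all counts must be whole numbers")
  p <- phyper(a - 1, m = a + b, n = c + d, k = a + c, lower.tail = FALSE)
  if (isTRUE(haldane)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    or <- ifelse(b * c > 0, (a * d) / (b * c),
                 ifelse(a * d > 0, Inf, ifelse(b * c > 0, 0, NaN)))
    or[b * c == 0 & a * d == 0] <- NaN
  }
  tibble::tibble(a = a, b = b, c = c, d = d, odds_ratio = or, p_value = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; input order is preserved and
#' `NA`s propagate.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent groups. When the combined sample
#' size is at most `exact_max` the p-value comes from exhaustive enumeration
#' of all group assignments (correct under ties); otherwise from the normal
#' approximation with tie-corrected variance, without continuity correction.
#' Two-sided p is twice the smaller tail, capped at 1.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact_max Combined size at or below which enumeration is used.
#' @return A tibble with `statistic` (U for `x`), `p_value`, `method`.
#' @examples
#' mann_whitney_two_sided(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_two_sided <- function(x, y, exact_max = 12) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  if (any(!is.finite(c(x, y)))) abort("values must be finite")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n <= exact_max) {
    idx <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
    method <- "exact"
  } else {
    ties <- table(pooled)
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (u_obs - mu) / sqrt(sig2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  tibble::tibble(statistic = u_obs, p_value = p, method = method)
}

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Paired comparison via signed ranks of the within-pair differences.
#' Zero differences are dropped (their count is reported). Small samples
#' (at most `exact_max` non-zero pairs) use exhaustive sign-pattern
#' enumeration, which remains exact under tied magnitudes; larger samples use
#' the tie-corrected normal approximation.
#'
#' @param before,after Equal-length numeric vectors of paired observations.
#' @param exact_max Non-zero pair count at or below which enumeration is used.
#' @return A tibble with `statistic` (V, the positive-rank sum), `p_value`,
#'   `n_zero` (dropped pairs) and `method`.
#' @examples
#' wilcoxon_paired_two_sided(1:10, 1:10 + 2)
#' @export
wilcoxon_paired_two_sided <- function(before, after, exact_max = 12) {
  before <- as.numeric(before); after <- as.numeric(after)
  if (length(before) != length(after))
    abort("`before` and `after` must have equal length")
  if (length(before) < 1) abort("need at least one pair")
  if (any(!is.finite(c(before, after)))) abort("values must be finite")
  d <- after - before
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warn("all paired differences are zero; p-value reported as 1")
    return(tibble::tibble(statistic = 0, p_value = 1, n_zero = n_zero,
                          method = "degenerate"))
  }
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  if (n <= exact_max) {
    # all 2^n sign patterns; V = sum of ranks assigned positive sign
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.numeric(signs %*% r)
    eps <- 1e-9
    p <- min(1, 2 * min(mean(v_all <= v_obs + eps), mean(v_all >= v_obs - eps)))
    method <- "exact"
  } else {
    ties <- table(abs(d))
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (v_obs - mu) / sqrt(sig2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  tibble::tibble(statistic = v_obs, p_value = p, n_zero = n_zero,
                 method = method)
}

#' Pearson chi-square test of independence
#'
#' Two-sided chi-square test on an r x c contingency table, without
#' continuity correction.
#'
#' @param tab Matrix of non-negative counts, at least 2 x 2.
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_independence(matrix(c(10, 0, 0, 10), 2))
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) abort("table must be at least 2 x 2")
  if (any(!is.finite(tab)) || any(tab < 0))
    abort("counts must be finite and non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    abort("table has a zero row or column margin")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value))
}
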