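# Independent oracles used to pin expected values. Each one is a deliberately
# naive direct computation, kept free of any package internals.

# Upper-tail hypergeometric probability P(X >= a) for a 2x2 table with fixed
# margins, by direct enumeration of the hypergeometric pmf.
hyper_tail_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  k1 <- a + b   # row margin (query set size)
  k2 <- a + c   # column margin (property size)
  ks <- max(0, k1 + k2 - n):min(k1, k2)
  pmf <- choose(k1, ks) * choose(n - k1, k2 - ks) / choose(n, k2)
  sum(pmf[ks >= a])
}

# Benjamini-Hochberg step-up by the direct formula:
# adj_(i) = min_{k >= i} m * p_(k) / k, mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- rev(cummin(rev(m * ps / seq_len(m))))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Two-group log-rank statistic by explicit risk tables at each distinct
# event time: sum over times of (O1 - E1), with hypergeometric variance.
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(all(g %in% 1:2))
  dt <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (tt in dt) {
    at_risk <- time >= tt
    n1 <- sum(at_risk & g == 1)
    n2 <- sum(at_risk & g == 2)
    d1 <- sum(time == tt & event == 1 & g == 1)
    d2 <- sum(time == tt & event == 1 & g == 2)
    n <- n1 + n2
    d <- d1 + d2
    if (n < 1) next
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (o_minus_e^2) / v
}

# Weighted GSEA running-sum enrichment score by walking the full ranked list.
es_oracle <- function(metric, in_set, weighted = TRUE) {
  ord <- order(metric, decreasing = TRUE)
  hit <- in_set[ord]
  w <- if (weighted) abs(metric[ord]) else rep(1, length(metric))
  w[!hit] <- 0
  inc <- w / sum(w)
  dec <- as.numeric(!hit) / sum(!hit)
  running <- cumsum(inc - dec)
  running[which.max(abs(running))]
}

# Tiny toy expression table builder: genes x samples. A plain vector is
# interpreted gene-by-gene (row-major); a matrix is used as-is.
toy_expr <- function(values, genes, samples) {
  m <- if (is.matrix(values)) values
       else matrix(values, nrow = length(genes), ncol = length(samples),
                   byrow = TRUE)
  colnames(m) <- samples
  dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(m))
}
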