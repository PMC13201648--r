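make_pairs <- function(n) {
  tibble::tibble(base = sprintf("b%02d", 1:n), treated = sprintf("t%02d", 1:n))
}

test_that("paired differential expression recovers exact shifts", {
  withr::with_seed(3, {
    n <- 5
    base <- toy_expr(rnorm(3 * n, 8), c("A", "B", "C"), sprintf("b%02d", 1:n))
    same <- base
    names(same) <- c("gene", sprintf("t%02d", 1:n))
    r <- differential_expression_paired(base, same, make_pairs(n))
    expect_equal(r$log2fc, rep(0, 3))
    expect_false(any(r$significant))
    shifted <- same
    shifted[shifted$gene == "B", -1] <- shifted[shifted$gene == "B", -1] + 2
    r2 <- differential_expression_paired(base, shifted, make_pairs(n))
    expect_equal(r2$log2fc[r2$gene == "B"], 2)
  })
  expect_error(
    differential_expression_paired(
      toy_expr(1:6, c("A", "B"), c("b01", "b02", "b03")),
      toy_expr(1:6, c("A", "B"), c("t01", "t02", "t99")),
      make_pairs(3)),
    "missing mates.*t03")
})

test_that("FDR column reproduces bh_fdr applied to the p column", {
  withr::with_seed(9, {
    n <- 8
    base <- toy_expr(rnorm(20 * n, 6), sprintf("g%02d", 1:20), sprintf("b%02d", 1:n))
    tr <- toy_expr(rnorm(20 * n, 6), sprintf("g%02d", 1:20), sprintf("t%02d", 1:n))
    r <- differential_expression_paired(base, tr, make_pairs(n))
    expect_equal(r$fdr, bh_fdr(r$p_value))
  })
})

test_that("planted differential genes are detected with controlled false flags", {
  withr::with_seed(17, {
    n_pairs <- 15; n_null <- 2000; n_de <- 100
    genes <- sprintf("g%04d", 1:(n_null + n_de))
    bm <- matrix(rnorm((n_null + n_de) * n_pairs, 7, 0.5), ncol = n_pairs)
    tm <- bm + matrix(rnorm(length(bm), 0, 0.5), ncol = n_pairs)
    tm[1:n_de, ] <- tm[1:n_de, ] - 1.5  # planted repression
    base <- toy_expr(bm, genes, sprintf("b%02d", 1:n_pairs))
    tr <- toy_expr(tm, genes, sprintf("t%02d", 1:n_pairs))
    r <- differential_expression_paired(base, tr, make_pairs(n_pairs))
    hits <- r$gene[r$significant]
    recall <- sum(hits %in% genes[1:n_de])
    false_flags <- sum(!hits %in% genes[1:n_de])
    expect_gte(recall, 90)
    expect_lte(false_flags, 0.05 * length(hits))
  })
})

test_that("GSEA enrichment score matches the brute-force running sum", {
  withr::with_seed(19, {
    # small universe, unit weights: hand-evaluable running sum
    metric <- c(5, 4, 3, 2, 1, -1, -2, -3)
    names <- paste0("g", 1:8)
    ranked <- tibble::tibble(gene = names, metric = metric)
    set <- list(top = c("g1", "g2", "g3"))
    r <- gsea_preranked(ranked, set, n_perm = 200, seed = 1, weighted = FALSE)
    expect_equal(r$es, es_oracle(metric, names %in% set$top, weighted = FALSE),
                 tolerance = 1e-12)
    # weighted ES against the oracle on random data
    for (i in 1:5) {
      m <- rnorm(40)
      g <- sprintf("r%02d", 1:40)
      s <- sample(g, 8)
      r2 <- gsea_preranked(tibble::tibble(gene = g, metric = m),
                           list(s = s), n_perm = 50, seed = i)
      expect_equal(r2$es, es_oracle(m, g %in% s), tolerance = 1e-12)
    }
  })
})

test_that("GSEA ES agrees with the fgsea reference implementation", {
  skip_if_not_installed("fgsea")
  withr::with_seed(23, {
    for (i in 1:5) {
      m <- sort(rnorm(60), decreasing = TRUE)
      g <- sprintf("x%02d", 1:60)
      s <- sample(g, 10)
      ours <- gsea_preranked(tibble::tibble(gene = g, metric = m),
                             list(s = s), n_perm = 10, seed = i)$es
      ref <- fgsea::calcGseaStat(m, selectedStats = which(g %in% s),
                                 gseaParam = 1)
      expect_equal(ours, ref, tolerance = 1e-8)
    }
  })
})

test_that("a maximally enriched set gets positive ES and the smallest p", {
  withr::with_seed(29, {
    m <- sort(rnorm(100), decreasing = TRUE)
    g <- sprintf("y%03d", 1:100)
    r <- gsea_preranked(tibble::tibble(gene = g, metric = m),
                        list(top5 = g[1:5]), n_perm = 1000, seed = 7)
    expect_gt(r$es, 0)
    # the achievable floor of the sign-matched doubled permutation p
    expect_lte(r$p_value, 0.01)
    expect_true(all(r$leading_edge[[1]] %in% g[1:5]))
  })
})

test_that("unit-weight ES is invariant to monotone metric rescaling", {
  withr::with_seed(31, {
    m <- rnorm(30); g <- sprintf("z%02d", 1:30); s <- sample(g, 6)
    e1 <- gsea_preranked(tibble::tibble(gene = g, metric = m),
                         list(s = s), n_perm = 10, seed = 1, weighted = FALSE)$es
    e2 <- gsea_preranked(tibble::tibble(gene = g, metric = exp(m) + 5),
                         list(s = s), n_perm = 10, seed = 1, weighted = FALSE)$es
    expect_equal(e1, e2, tolerance = 1e-12)
  })
  expect_warning(
    gsea_preranked(tibble::tibble(gene = c("a", "b", "c"), metric = 3:1),
                   list(bad = "a"), n_perm = 10),
    "skipped")
})

test_that("association coefficients flip sign when labels swap", {
  withr::with_seed(37, {
    n <- 60
    expr <- toy_expr(rnorm(5 * n), sprintf("g%d", 1:5), sprintf("s%02d", 1:n))
    sd_ <- tibble::tibble(sample = sprintf("s%02d", 1:n),
                          response = sample(c("NR", "Resp"), n, TRUE),
                          arm = sample(c("mono", "combo"), n, TRUE))
    r1 <- response_gene_association(expr, sd_, covariates = "arm")
    sd2 <- dplyr::mutate(sd_, response = ifelse(response == "NR", "Resp", "NR"))
    r2 <- response_gene_association(expr, sd2, covariates = "arm")
    expect_equal(r1$log2_odds, -r2$log2_odds, tolerance = 1e-8)
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-8)
  })
})

test_that("perfect separation yields a sentinel, single class errors", {
  n <- 20
  expr <- toy_expr(rep(c(1, 0), each = n / 2), "g1", sprintf("s%02d", 1:n))
  sd_ <- tibble::tibble(sample = sprintf("s%02d", 1:n),
                        response = rep(c("Resp", "NR"), each = n / 2))
  r <- response_gene_association(expr, sd_)
  expect_true(r$separated)
  expect_true(is.na(r$log2_odds))
  expect_error(
    response_gene_association(expr, dplyr::mutate(sd_, response = "Resp")),
    "both response classes")
})

test_that("a covariate that explains the labels absorbs the signal", {
  withr::with_seed(41, {
    n <- 120
    arm <- rep(c("mono", "combo"), each = n / 2)
    # response driven by arm; gene expression correlated with arm only
    resp <- ifelse(arm == "mono", "NR", "Resp")
    flip <- sample(n, 20); resp[flip] <- ifelse(resp[flip] == "NR", "Resp", "NR")
    gvals <- ifelse(arm == "mono", 0, 1) + rnorm(n, 0, 0.5)
    expr <- toy_expr(gvals, "g1", sprintf("s%03d", 1:n))
    sd_ <- tibble::tibble(sample = sprintf("s%03d", 1:n), response = resp,
                          arm = arm)
    r_adj <- response_gene_association(expr, sd_, covariates = "arm")
    expect_gt(r_adj$p_value, 0.05)
  })
})

test_that("TF enrichment ranks planted regulators by odds ratio", {
  withr::with_seed(43, {
    universe <- sprintf("u%03d", 1:100)
    query <- universe[1:10]
    lib <- dplyr::bind_rows(
      tibble::tibble(tf = "TF_hit", target = c(universe[1:8], universe[90:101 - 1])),
      tibble::tibble(tf = "TF_same", target = query),
      tibble::tibble(tf = "TF_disj", target = universe[50:69])
    )
    r <- tf_enrichment(query, lib, universe)
    hit <- r[r$tf == "TF_hit", ]
    # universe=100, query=10, targets=20, overlap=8: enumeration oracle
    expect_equal(hit$p_value, hyper_tail_oracle(8, 2, 12, 78), tolerance = 1e-10)
    expect_identical(r$odds_ratio[r$tf == "TF_same"], Inf)
    expect_equal(r$tf[1], "TF_same")
    disj <- r[r$tf == "TF_disj", ]
    expect_lte(disj$odds_ratio, 1)
    expect_gte(disj$p_value, 0.5)
    expect_equal(r$fdr, bh_fdr(r$p_value))
    expect_error(tf_enrichment(c(query, "NOT_IN"), lib, universe), "subset")
  })
})
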