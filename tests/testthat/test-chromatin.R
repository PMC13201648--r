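test_that("differential peak classes follow the printed cutoffs", {
  p <- tibble::tibble(log2fc = c(1.5, 0, 1.5, -1.2, -0.5, 0.2),
                      fdr = c(0.01, 0.99, 0.2, 0.001, 1, 0.5))
  r <- classify_differential_peaks(p)
  expect_equal(as.character(r$peak_class),
               c("up", "unchanged", "excluded", "down", "excluded", "unchanged"))
  # exhaustive, mutually exclusive partition
  expect_equal(sum(attr(r, "class_counts")), nrow(p))
  expect_false(any(is.na(r$peak_class)))
})

test_that("peak cap passes small sets through and samples deterministically", {
  cfg <- threshold_config(peak_cap = 50)
  p <- tibble::tibble(peak_id = sprintf("p%03d", 1:40), log2fc = 0, fdr = 0.5)
  expect_identical(cap_peaks(p, cfg)$peak_id, p$peak_id)
  big <- tibble::tibble(peak_id = sprintf("p%03d", 1:120), log2fc = 0, fdr = 0.5)
  s1 <- cap_peaks(big, cfg, seed = 9)
  s2 <- cap_peaks(big, cfg, seed = 9)
  expect_equal(nrow(s1), 50)
  expect_identical(s1$peak_id, s2$peak_id)
  # original order preserved
  expect_true(all(diff(match(s1$peak_id, big$peak_id)) > 0))
})

test_that("motif enrichment score is %TP - %FP with Fisher p", {
  hits <- tibble::tibble(peak_id = sprintf("p%02d", 1:20),
                         M = c(rep(TRUE, 8), rep(FALSE, 2),
                               rep(TRUE, 2), rep(FALSE, 8)))
  fg <- sprintf("p%02d", 1:10); bg <- sprintf("p%02d", 11:20)
  r <- motif_enrichment(hits, fg, bg)
  expect_equal(r$score, 60)
  expect_equal(r$p_value, hyper_tail_oracle(8, 2, 2, 8), tolerance = 1e-10)
  # bounds and degenerate cases
  hits2 <- tibble::tibble(peak_id = hits$peak_id,
                          all_fg = c(rep(TRUE, 10), rep(FALSE, 10)),
                          same = rep(c(TRUE, FALSE), 10))
  r2 <- motif_enrichment(hits2, fg, bg)
  expect_equal(r2$score[r2$motif == "all_fg"], 100)
  expect_equal(r2$score[r2$motif == "same"], 0)
  expect_true(all(r2$score >= -100 & r2$score <= 100))
  expect_error(motif_enrichment(hits, fg, fg), "disjoint")
  expect_error(motif_enrichment(hits, character(0), bg), "non-empty")
})

test_that("enrichment score sign agrees with the odds ratio direction", {
  withr::with_seed(47, {
    hits <- tibble::tibble(peak_id = sprintf("q%03d", 1:200),
                           m1 = runif(200) < 0.4, m2 = runif(200) < 0.2)
    fg <- hits$peak_id[1:80]; bg <- hits$peak_id[81:200]
    r <- motif_enrichment(hits, fg, bg)
    ok <- is.finite(r$odds_ratio) & r$score != 0
    expect_true(all((r$score[ok] > 0) == (r$odds_ratio[ok] > 1)))
  })
})

test_that("motif co-occurrence partitions into exclusive categories", {
  hits <- tibble::tibble(peak_id = c("p1", "p2", "p3", "p4"),
                         A = c(TRUE, FALSE, TRUE, TRUE),
                         B = c(FALSE, TRUE, TRUE, FALSE))
  r <- motif_cooccurrence_partition(hits, "A", "B")
  expect_equal(r$fraction, c(2 / 4, 1 / 4, 1 / 4))
  expect_equal(sum(r$fraction), 1)
  # swapping motifs swaps the one-sided categories
  r2 <- motif_cooccurrence_partition(hits, "B", "A")
  expect_equal(r2$n[r2$category == "a_only"], r$n[r$category == "b_only"])
  expect_equal(r2$n[r2$category == "both"], r$n[r$category == "both"])
  none <- tibble::tibble(peak_id = "p9", A = FALSE, B = FALSE)
  expect_error(motif_cooccurrence_partition(none, "A", "B"), "no peak carries")
})

test_that("peak-to-gene proximity uses TSS-to-interval distance", {
  genes <- tibble::tibble(gene = c("near", "far"), chrom = "chrS",
                          tss = c(5000, 5000))
  cfg1 <- threshold_config(min_sites_per_gene = 1)
  near_peak <- tibble::tibble(chrom = "chrS", start = 7500, end = 7800,
                              peak_id = "p1")
  far_peak <- tibble::tibble(chrom = "chrS", start = 8001, end = 8200,
                             peak_id = "p2")
  expect_true(map_peaks_to_genes(near_peak, genes[1, ], cfg1)$retained)  # d=2500
  expect_false(map_peaks_to_genes(far_peak, genes[1, ], cfg1)$retained)  # d=3001
  # ">1 site" rule: one qualifying site excluded, two retained
  two <- dplyr::bind_rows(near_peak,
                          tibble::tibble(chrom = "chrS", start = 4000,
                                         end = 4200, peak_id = "p3"))
  cfg2 <- threshold_config(min_sites_per_gene = 2)
  expect_false(map_peaks_to_genes(near_peak, genes[1, ], cfg2)$retained)
  expect_true(map_peaks_to_genes(two, genes[1, ], cfg2)$retained)
  # TSS inside a peak counts at distance 0
  inside <- tibble::tibble(chrom = "chrS", start = 4900, end = 5100,
                           peak_id = "p4")
  expect_equal(map_peaks_to_genes(inside, genes[1, ], cfg1)$n_sites, 1)
  expect_error(
    map_peaks_to_genes(dplyr::mutate(near_peak, chrom = "1"), genes, cfg1),
    "no shared chromosome")
})

test_that("expression trend test reports direction and handles ties", {
  expr <- tibble::tibble(gene = sprintf("g%02d", 1:10),
                         parental = 1:10, m2 = 1:10, resistant = 1:10 + 2)
  sets <- list(all = expr$gene)
  suppressWarnings(r <- expression_trend_test(sets, expr))
  expect_equal(r$p_value[r$comparison == "parental vs m2"], 1)
  pr <- r[r$comparison == "parental vs resistant", ]
  expect_lt(pr$p_value, 0.01)
  expect_equal(pr$median_diff, 2)
  # swapping the conditions flips the effect sign, p unchanged
  r2 <- suppressWarnings(
    expression_trend_test(sets, expr, conditions = c("resistant", "parental")))
  expect_equal(r2$median_diff, -pr$median_diff)
  expect_equal(r2$p_value, pr$p_value)
  expect_error(expression_trend_test(list(s = "nope"), expr), "absent")
})
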