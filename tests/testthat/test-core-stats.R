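test_that("one-sided Fisher p equals the hypergeometric tail", {
  # degenerate empty query row: the tail is the full mass
  expect_equal(fisher_exact_one_sided(0, 0, 0, 10)$p_value, 1)
  # fully concordant table: only one table in the tail
  expect_equal(fisher_exact_one_sided(10, 0, 0, 10)$p_value,
               1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisher_exact_one_sided(8, 2, 2, 8)$p_value,
               hyper_tail_oracle(8, 2, 2, 8), tolerance = 1e-12)
})

test_that("Fisher odds ratio uses the cross product with infinity sentinel", {
  r <- fisher_exact_one_sided(c(6, 5, 0), c(2, 0, 3), c(1, 2, 2), c(7, 4, 6))
  expect_equal(r$odds_ratio[1], (6 * 7) / (2 * 1))
  expect_identical(r$odds_ratio[2], Inf)
  expect_equal(r$odds_ratio[3], 0)
  rh <- fisher_exact_one_sided(5, 0, 2, 4, haldane = TRUE)
  expect_equal(rh$odds_ratio, (5.5 * 4.5) / (0.5 * 2.5))
})

test_that("Fisher input validation rejects bad counts", {
  expect_error(fisher_exact_one_sided(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact_one_sided(1.5, 2, 3, 4), "whole")
})

test_that("BH adjustment matches the direct step-up formula and is idempotent", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  withr::with_seed(11, {
    for (i in 1:20) {
      p <- runif(sample(1:40, 1))
      adj <- bh_fdr(p)
      expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
      expect_true(all(adj >= 0 & adj <= 1))
      expect_true(adj[which.min(p)] >= min(p))
    }
  })
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Mann-Whitney exact enumeration matches hand-counted assignments", {
  r <- mann_whitney_two_sided(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 2 / 20)  # 2 of the 20 rank assignments are as extreme
  expect_identical(r$method, "exact")
  # identical multisets: no separation
  expect_gte(mann_whitney_two_sided(c(1, 2, 3), c(1, 2, 3))$p_value, 0.99)
})

test_that("Mann-Whitney is symmetric and agrees with stats::wilcox.test", {
  withr::with_seed(21, {
    for (i in 1:10) {
      x <- rnorm(sample(3:9, 1))
      y <- rnorm(sample(3:9, 1))
      expect_equal(mann_whitney_two_sided(x, y)$p_value,
                   mann_whitney_two_sided(y, x)$p_value, tolerance = 1e-12)
      if (length(x) + length(y) <= 12) {
        expect_equal(mann_whitney_two_sided(x, y)$p_value,
                     wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-10)
      }
    }
    # large-sample branch against the uncorrected normal approximation
    x <- rnorm(30); y <- rnorm(25, 0.5)
    r <- mann_whitney_two_sided(x, y)
    expect_identical(r$method, "normal_approx")
    expect_equal(r$p_value,
                 wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value,
                 tolerance = 1e-10)
  })
  expect_error(mann_whitney_two_sided(numeric(0), 1:3), "non-empty")
})

test_that("paired signed-rank test handles zeros, shifts and symmetry", {
  expect_warning(r0 <- wilcoxon_paired_two_sided(1:5, 1:5), "zero")
  expect_equal(r0$p_value, 1)
  expect_equal(r0$n_zero, 5)
  # constant positive shift, n = 10: only the all-positive sign pattern is as
  # extreme in the upper tail, so p = 2/2^10
  r <- wilcoxon_paired_two_sided(1:10, 1:10 + 3)
  expect_equal(r$p_value, 2 / 1024)
  expect_equal(r$statistic, 55)
  withr::with_seed(31, {
    for (i in 1:10) {
      a <- rnorm(8); b <- rnorm(8)
      expect_equal(wilcoxon_paired_two_sided(a, b)$p_value,
                   wilcoxon_paired_two_sided(b, a)$p_value, tolerance = 1e-12)
      expect_equal(wilcoxon_paired_two_sided(a, b)$p_value,
                   wilcox.test(b, a, paired = TRUE, exact = TRUE)$p.value,
                   tolerance = 1e-10)
    }
    a <- rnorm(25); b <- a + rnorm(25, 0.3)
    r <- wilcoxon_paired_two_sided(a, b)
    expect_identical(r$method, "normal_approx")
    expect_equal(r$p_value,
                 wilcox.test(b, a, paired = TRUE, exact = FALSE,
                             correct = FALSE)$p.value,
                 tolerance = 1e-10)
  })
  expect_error(wilcoxon_paired_two_sided(1:3, 1:4), "equal length")
})

test_that("chi-square independence test matches closed forms", {
  r <- chi_square_independence(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r$statistic, 20)
  r2 <- chi_square_independence(matrix(c(5, 5, 5, 5), 2))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)
  m <- matrix(c(3, 7, 9, 1, 5, 5), nrow = 2)
  expect_equal(chi_square_independence(m)$statistic,
               chi_square_independence(m[2:1, ])$statistic)
  expect_error(chi_square_independence(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_error(chi_square_independence(matrix(1:3, 1)), "2 x 2")
})

test_that("threshold registry validates and round-trips through YAML", {
  cfg <- threshold_config()
  expect_equal(cfg$pfs_responder_min, 2)
  expect_equal(cfg$vaf_mutant_min, 0.05)
  expect_equal(cfg$peak_cap, 60000)
  expect_equal(cfg$gene_window, 3000)
  expect_error(threshold_config(vaf_mutant_min = 0), "vaf_mutant_min")
  expect_error(threshold_config(cnv_loss_max = 2), "cnv_loss_max")
  expect_error(threshold_config(peak_cap = 0), "peak_cap")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_threshold_config(threshold_config(tf_top_k = 5), path)
  cfg2 <- read_threshold_config(path)
  expect_equal(cfg2$tf_top_k, 5)
  expect_s3_class(cfg2, "lumishift_thresholds")
  yaml::write_yaml(list(bogus_key = 1), path)
  expect_error(read_threshold_config(path), "unknown threshold keys")
})
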