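test_that("Shapiro-Wilk gate separates normal from skewed samples", {
  set.seed(41)
  expect_equal(normality_gate(rnorm(50)), "normal")
  expect_equal(normality_gate(rexp(50)), "non-normal")
  expect_warning(g <- normality_gate(rep(1.2, 10)), "zero-variance")
  expect_equal(g, "non-normal")
  expect_error(normality_gate(c(1, 2)), "at least 3")
})

test_that("two-sample test gates, identical samples and exact branch", {
  set.seed(8)
  x <- rnorm(12, 1, 0.1)
  res <- two_sample_test(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$test, "pooled t")

  # strongly skewed data routes to the rank test
  set.seed(9)
  res2 <- two_sample_test(rlnorm(30, sdlog = 1.5), rlnorm(30, sdlog = 1.5) + 0.5)
  expect_equal(res2$test, "Mann-Whitney U")

  # fully separated small samples: exact two-sided p = 2/20
  res3 <- two_sample_test(c(1, 2, 3), c(4, 5, 6), method = "mann_whitney")
  expect_equal(res3$p_value, 0.1)
  expect_equal(res3$statistic, 0)

  expect_error(two_sample_test(1, c(1, 2)), "at least 2")
})

test_that("Mann-Whitney exact branch matches full enumeration", {
  set.seed(77)
  for (rep in 1:20) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    x <- round(rnorm(n1), 6); y <- round(rnorm(n2, 0.5), 6)
    got <- two_sample_test(x, y, method = "mann_whitney")$p_value
    expect_equal(got, mw_exact_p_oracle(x, y), tolerance = 1e-12,
                 info = sprintf("rep %d (n1=%d, n2=%d)", rep, n1, n2))
  }
})

test_that("Wilcoxon signed-rank exact branch matches sign enumeration", {
  # all-positive differences 1..5: 2/32 sign patterns as extreme
  res <- paired_test(rep(0, 5), c(1, 2, 3, 4, 5), method = "wilcoxon")
  expect_equal(res$p_value, 0.0625)

  set.seed(78)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    d <- round(rnorm(n, 0.3), 6)
    got <- paired_test(rep(0, n), d, method = "wilcoxon")$p_value
    expect_equal(got, signrank_exact_p_oracle(d), tolerance = 1e-12,
                 info = sprintf("rep %d (n=%d)", rep, n))
  }
})

test_that("paired test edge cases and closed-form power case", {
  x <- c(1.01, 1.05, 0.99, 1.1)
  expect_warning(res <- paired_test(x, x), "zero")
  expect_equal(res$p_value, 1)

  expect_warning(res0 <- paired_test(rep(1, 4), rep(1, 4)), "zero")
  expect_equal(res0$p_value, 1)

  # differences with mean 0.066, SD 0.08, n = 15 are significant
  set.seed(12)
  d <- as.vector(scale(rnorm(15))) * 0.08 + 0.066
  res2 <- paired_test(rep(0, 15), d, method = "paired_t")
  expect_equal(res2$statistic, 0.066 / (0.08 / sqrt(15)), tolerance = 1e-9)
  expect_lt(res2$p_value, 0.05)
})

test_that("summary t-test matches closed form and numeric t integration", {
  r_hc <- summary_ttest(1.003, 0.108, 15, 1.263, 0.161, 8)
  expect_equal(r_hc$statistic, -4.635, tolerance = 1e-3)
  expect_equal(r_hc$df, 21)
  expect_equal(r_hc$p_value, t_pvalue_numeric(r_hc$statistic, 21),
               tolerance = 1e-9)
  expect_equal(r_hc$p_value, 1.4e-4, tolerance = 0.02)

  nr_hc <- summary_ttest(0.960, 0.079, 6, 1.263, 0.161, 8)
  expect_equal(nr_hc$statistic, -4.215, tolerance = 1e-3)
  expect_equal(nr_hc$df, 12)
  expect_equal(nr_hc$p_value, 1.2e-3, tolerance = 0.02)

  expect_equal(summary_ttest(1, 0.1, 10, 1, 0.1, 10)$p_value, 1)
  expect_error(summary_ttest(1, 0, 10, 1, 0.1, 10), "positive")
})

test_that("summary t-test equals the sample-level pooled t to 1e-12", {
  set.seed(31)
  for (rep in 1:10) {
    x <- rnorm(sample(5:20, 1), 1, 0.12)
    y <- rnorm(sample(5:20, 1), 1.1, 0.2)
    a <- two_sample_test(x, y, method = "pooled_t")
    b <- summary_ttest(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
    expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  }
})

test_that("BH adjustment follows the cumulative-minimum formula", {
  expect_equal(bh_adjust(c(1.4e-4, 1.2e-3, 0.3852)),
               c(4.2e-4, 1.8e-3, 0.3852), tolerance = 1e-12)
  expect_equal(bh_adjust(0.07), 0.07)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(55)
  for (rep in 1:20) {
    p <- runif(sample(2:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

test_that("Spearman correlation handles ranks, ties and degeneracy", {
  x <- c(0.3, 1.2, 2.5, 3.1, 4.8)
  expect_equal(spearman_corr(x, x)$rho, 1)
  expect_equal(spearman_corr(x, 10 - x)$rho, -1)
  expect_equal(spearman_corr(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho, 0.6)
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
  # midranks under ties still give a finite result
  tied <- spearman_corr(c(1, 1, 2, 3, 4, 5), c(2, 3, 3, 5, 6, 8))
  expect_true(is.finite(tied$rho) && tied$rho > 0)
})

test_that("cohort-level comparison wrappers assemble BH families", {
  co <- simulate_cohort(seed = 23)
  base <- baseline_group_tests(co)
  expect_equal(nrow(base), 3)
  expect_setequal(base$comparison, c("R vs HC", "NR vs HC", "R vs NR"))
  expect_true(all(base$p_adjusted >= base$p_value - 1e-15))
  expect_true(all(base$p_adjusted <= 1))

  long <- longitudinal_group_tests(co)
  expect_true(all(c("R: t0 vs t1_postTT", "R: t0 vs t3_postVPS",
                    "NR: t0 vs t1_postTT") %in% long$comparison))
  expect_true(all(long$p_adjusted >= long$p_value - 1e-15))

  # covariate correlations run on attached columns
  t0 <- co[co$timepoint == "t0", ]
  set.seed(4)
  t0$evans_index <- 0.45 - 0.2 * t0$alps_index + rnorm(nrow(t0), 0, 0.02)
  cc <- covariate_correlations(t0)
  expect_equal(nrow(cc), 1)
  expect_lt(cc$rho, 0)
})

test_that("summary-based baseline family reproduces published footnotes", {
  res <- summary_group_tests()
  expect_equal(round(res$p_adjusted[res$comparison == "R vs HC"], 4), 4e-04)
  expect_equal(round(res$p_adjusted[res$comparison == "NR vs HC"], 4), 0.0018)
})
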