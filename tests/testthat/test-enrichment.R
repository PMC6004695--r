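test_that("Yates chi-square matches hand-computed and degenerate cases", {
  # balanced table: O = E everywhere -> statistic 0
  expect_equal(yates_chi_square(c(10, 10, 10, 10))$statistic, 0)
  # hand-computed continuity-corrected value
  expect_equal(yates_chi_square(c(20, 5, 5, 20))$statistic, 15.68,
               tolerance = 1e-10)
  expect_error(yates_chi_square(c(0, 0, 5, 5)), "zero row")
  expect_error(yates_chi_square(c(-1, 2, 3, 4)), "non-negative")
})

test_that("correction term clamps at zero when |O - E| < 0.5", {
  # nearly balanced: |O - E| = 0.25 in every cell
  tab <- matrix(c(10, 10, 9, 11), nrow = 2, byrow = TRUE)
  expect_equal(yates_chi_square(tab)$statistic, 0)
  # R's chisq.test uses min(0.5, |O-E|), which is the same clamping
  expect_equal(yates_chi_square(tab)$p_value,
               suppressWarnings(chisq.test(tab, correct = TRUE)$p.value))
})

test_that("odds ratio is ad/bc with a Woolf interval and zero-cell handling", {
  expect_equal(odds_ratio(c(10, 10, 10, 10))$or, 1)
  expect_equal(odds_ratio(c(20, 5, 5, 20))$or, 16)
  or <- odds_ratio(c(20, 5, 5, 20))
  se <- sqrt(1 / 20 + 1 / 5 + 1 / 5 + 1 / 20)
  expect_equal(or$ci_lower, exp(log(16) - qnorm(0.975) * se), tolerance = 1e-12)
  # swapped rows invert the ratio
  expect_equal(odds_ratio(c(5, 20, 20, 5))$or, 1 / 16, tolerance = 1e-12)
  # Haldane-Anscombe correction for zero cells
  z <- odds_ratio(c(0, 10, 10, 10))
  expect_true(z$corrected)
  expect_equal(z$or, (0.5 * 10.5) / (10.5 * 10.5))
})

test_that("Kruskal-Wallis handles the textbook separation and identical groups", {
  expect_equal(kruskal_wallis(list(1:3, 4:6))$statistic, 3.857, tolerance = 1e-3)
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0,
               tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3)), "at least two")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("chi-square, Kruskal-Wallis and BH agree with stats:: to 1e-8", {
  set.seed(53)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 30) + 1L, nrow = 2)
    mine <- yates_chi_square(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = TRUE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)

    groups <- list(round(rnorm(sample(5:20, 1)), 1),
                   round(rnorm(sample(5:20, 1), mean = 0.5), 1),
                   round(rnorm(sample(5:20, 1)), 1))
    kw <- kruskal_wallis(groups)
    kref <- kruskal.test(groups)
    expect_equal(kw$statistic, unname(kref$statistic), tolerance = 1e-8)
    expect_equal(kw$p_value, kref$p.value, tolerance = 1e-8)

    p <- runif(sample(3:50, 1))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"), tolerance = 1e-8)
  }
})

test_that("bootstrap results are reproducible and flag fully significant sets", {
  universe <- setNames(rep(c(TRUE, FALSE), c(100, 900)),
                       sprintf("g%04d", 1:1000))
  a <- bootstrap_expression_enrichment(universe, names(universe)[1:50],
                                       n_boot = 499, sample_size = 100,
                                       seed = 7)
  b <- bootstrap_expression_enrichment(universe, names(universe)[1:50],
                                       n_boot = 499, sample_size = 100,
                                       seed = 7)
  expect_identical(a, b)
  # set of only-significant genes in a 10%-significant universe
  expect_equal(a$observed_percent, 100)
  expect_equal(a$percentile_label, "> 99.9")
  expect_equal(a$percentile, 100)
  expect_lt(a$bootstrap_mean + 4 * a$ci95_halfwidth, 100)
})

test_that("bootstrap validates its inputs", {
  universe <- setNames(rep(TRUE, 10), letters[1:10])
  expect_error(bootstrap_expression_enrichment(universe, character(),
                                               n_boot = 9, sample_size = 5),
               "empty gene set")
  expect_error(bootstrap_expression_enrichment(universe, "zz",
                                               n_boot = 9, sample_size = 5),
               "absent")
  expect_error(bootstrap_expression_enrichment(universe, "a",
                                               n_boot = 9, sample_size = 50),
               "exceeds")
})

test_that("percentile uses strict inequality (ties count as not-below)", {
  universe <- setNames(rep(c(TRUE, FALSE), 5), letters[1:10])
  # observed rate of any 2-gene set is one of 0/50/100%; with sample_size
  # equal to the universe, every replicate equals 50% exactly
  res <- bootstrap_expression_enrichment(universe, c("a", "c"),
                                         n_boot = 99, sample_size = 10,
                                         seed = 1)
  expect_equal(res$observed_percent, 100)
  expect_equal(res$percentile, 100)
  res_tied <- bootstrap_expression_enrichment(universe, c("a", "b"),
                                              n_boot = 99, sample_size = 10,
                                              seed = 1)
  expect_equal(res_tied$observed_percent, 50)
  expect_equal(res_tied$percentile, 0)  # ties are not below
})

test_that("set-vs-genome enrichment builds the inclusive 2x2 table", {
  calls <- data.frame(gene_id = sprintf("g%03d", 1:100),
                      significant = rep(c(TRUE, FALSE), c(20, 80)))
  set <- sprintf("g%03d", 1:10)  # all significant
  enr <- set_vs_genome_enrichment(calls, set)
  expect_equal(unname(enr$table[1, ]), c(10, 0))
  expect_equal(unname(enr$table[2, ]), c(20, 80))  # genome row includes set
  expect_gt(enr$odds_ratio$or, 1)
  disj <- set_vs_genome_enrichment(calls, set, disjoint = TRUE)
  expect_equal(unname(disj$table[2, ]), c(10, 80))
  expect_error(set_vs_genome_enrichment(calls, "absent"), "no gene-set member")
})

test_that("planted 2x enrichment is detected in most seeded runs", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    n <- 4000L
    in_set <- rep(c(TRUE, FALSE), c(400L, n - 400L))
    rate <- ifelse(in_set, 0.14, 0.07)
    calls <- data.frame(gene_id = sprintf("g%04d", 1:n),
                        significant = runif(n) < rate)
    enr <- set_vs_genome_enrichment(calls, calls$gene_id[in_set])
    hits <- hits + (enr$chi_square$p_value < 0.05 && enr$odds_ratio$or > 1)
  }
  expect_gte(hits, 19L)
})
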