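test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)  # single p unchanged
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # adjusted values never below raw, monotone after sorting by raw p
  set.seed(61)
  p <- runif(200)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  # null behavior: a uniform list adjusts to values near 1
  expect_gt(mean(adj > 0.5), 0.95)
})

test_that("direction calls split on adjusted p and fold-change sign", {
  tab <- data.frame(gene_id = c("up1", "dn1", "ns1", "zero"),
                    log2fc = c(1.2, -0.8, -0.8, 0),
                    padj = c(0.001, 0.04, 0.20, 0.01))
  expect_warning(d <- call_directions(tab), "log2 fold-change 0")
  expect_equal(as.character(d$direction), c("up", "down", "ns", NA))
})

test_that("orthogroup significance follows the any-paralog rule", {
  map <- data.frame(human_id = c("h1", "h1", "h2", "h3"),
                    orthogroup = c("og1", "og1", "og2", "og3"),
                    fish_id = c("f1a", "f1b", "f2a", "f3a"))
  dirs <- call_directions(data.frame(
    gene_id = c("f1a", "f1b", "f2a", "f3a", "stray"),
    log2fc = c(2, 0.5, -1, 1, 1),
    padj = c(0.01, 0.50, 0.90, 0.01, 0.01)))
  s <- orthogroup_summary(dirs, map)
  og <- s$orthogroups[match(c("og1", "og2", "og3"), s$orthogroups$orthogroup), ]
  expect_equal(og$significant, c(TRUE, FALSE, TRUE))  # one-of-two; none; singleton
  expect_equal(s$rates$n_significant[s$rates$level == "orthogroup"], 2L)
  expect_equal(s$rates$n_significant[s$rates$level == "paralog"], 2L)
  expect_equal(s$unmapped, "stray")
})

test_that("orthogroup significant count never exceeds the paralog count", {
  cfg <- sim_config(seed = 71, n_genes = 300, geneset_size = 30)
  de <- simulate_de_tables(cfg)
  s <- orthogroup_summary(call_directions(de$fish), de$map)
  expect_lte(s$rates$n_significant[s$rates$level == "orthogroup"],
             s$rates$n_significant[s$rates$level == "paralog"])
})

test_that("concordance counts at the paralog level and honors exclusions", {
  map <- data.frame(human_id = c("h1", "h1", "h2"),
                    orthogroup = c("og1", "og1", "og2"),
                    fish_id = c("f1a", "f1b", "f2a"))
  fish <- call_directions(data.frame(gene_id = c("f1a", "f1b", "f2a"),
                                     log2fc = c(2, -1, 1),
                                     padj = c(0.01, 0.01, 0.01)))
  human <- call_directions(data.frame(gene_id = c("h1", "h2"),
                                      log2fc = c(1, 1),
                                      padj = c(0.01, 0.01)))
  res <- concordance(fish, human, map)
  # both paralogs of h1 are scored independently against the human direction
  expect_equal(res$n_jointly_de, 3L)
  expect_equal(res$n_same_direction, 2L)
  expect_equal(res$percent_same_direction, 100 * 2 / 3)

  res2 <- concordance(fish, human, map, excluded_human = "h1")
  expect_equal(res2$n_jointly_de, 1L)
  expect_equal(res2$n_excluded_inconsistent, 1L)
  expect_error(concordance(fish, human, map[0, ]), "empty")
})

test_that("conflicting human reports are excluded by the aggregator", {
  r1 <- call_directions(data.frame(gene_id = c("h1", "h2"),
                                   log2fc = c(1, 1), padj = c(0.01, 0.01)))
  r2 <- call_directions(data.frame(gene_id = c("h1", "h3"),
                                   log2fc = c(-1, -2), padj = c(0.01, 0.01)))
  agg <- aggregate_human_directions(list(r1, r2))
  expect_equal(agg$excluded, "h1")  # up in one report, down in another
  expect_equal(as.character(agg$directions$direction[
    agg$directions$gene_id == "h2"]), "up")
  expect_equal(as.character(agg$directions$direction[
    agg$directions$gene_id == "h3"]), "down")
})

test_that("swapping up/down in both species preserves the concordance percent", {
  cfg <- sim_config(seed = 73, n_genes = 500, concordance_rate = 0.7,
                    geneset_size = 50)
  de <- simulate_de_tables(cfg)
  res <- concordance(call_directions(de$fish), call_directions(de$human),
                     de$map)
  flip <- function(t) { t$log2fc <- -t$log2fc; t }
  res_flipped <- concordance(call_directions(flip(de$fish)),
                             call_directions(flip(de$human)), de$map)
  expect_equal(res_flipped$percent_same_direction,
               res$percent_same_direction)
})

test_that("cross-model comparisons apply the pairwise Bonferroni factor", {
  res <- data.frame(model = c("a", "b", "c"),
                    n_de = c(43L, 2L, 30L), n_total = c(58L, 65L, 60L))
  out <- cross_model_comparison(res)
  expect_equal(nrow(out), 3L)
  expect_true(all(out$n_tests == 3L))
  expect_equal(out$p_bonferroni, pmin(1, out$p_raw * 3))
  # identical rates: corrected p caps at 1
  same <- cross_model_comparison(data.frame(model = c("a", "b"),
                                            n_de = c(10L, 10L),
                                            n_total = c(50L, 50L)))
  expect_equal(same$p_bonferroni, 1)
  expect_equal(same$statistic, 0)
  expect_error(cross_model_comparison(data.frame(model = "a", n_de = 1L,
                                                 n_total = 10L)),
               "at least|>= 2|2L")
})

test_that("planted concordance rate is recovered from large simulations", {
  cfg <- sim_config(seed = 79, n_genes = 4000, de_fraction = 0.5,
                    concordance_rate = 0.6, geneset_size = 500)
  de <- simulate_de_tables(cfg)
  res <- concordance(call_directions(de$fish), call_directions(de$human),
                     de$map)
  expect_gte(res$n_jointly_de, 2000L)
  expect_lt(abs(res$percent_same_direction - 60), 3)
})
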