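test_that("site filters apply the mask, indel-flank and coverage rules", {
  counts <- make_counts("chr1", c(5L, 45L, 100L, 110L, 111L, 200L),
                        n1 = c(20L, 20L, 20L, 20L, 20L, 10L),
                        alt1 = 1L, n2 = 20L, alt2 = 1L)
  ann <- gene_annotation(
    genes = one_gene(end = 500L),
    masks = data.frame(chrom = "chr1", start = 40L, end = 50L),
    # indel affects base 90 (0-based interval [89, 90)); flank 10 bp
    indels = data.frame(chrom = "chr1", start = 89L, end = 90L))
  f <- filter_sites(counts, ann, min_individuals = 6L)
  # site 45 masked; site 100 is exactly 10 bp from the indel base -> removed;
  # 110/111 are 20/21 bp away -> retained; site 200 has 5 individuals in pop1
  expect_equal(f$pos, c(5L, 110L, 111L))
  log <- attr(f, "filter_log")
  expect_equal(unname(log["masked"]), 1L)
  expect_equal(unname(log["near_indel"]), 1L)
  expect_equal(unname(log["low_coverage"]), 1L)
})

test_that("filters warn on unknown chromosomes and merge overlapping masks", {
  counts <- make_counts("chr1", c(10L, 30L), 20L, 5L, 20L, 5L)
  ann <- gene_annotation(
    genes = one_gene(),
    masks = data.frame(chrom = c("chr1", "chr1", "chrX"),
                       start = c(5L, 8L, 0L), end = c(12L, 15L, 100L)))
  expect_warning(f <- filter_sites(counts, ann), "chrX")
  expect_equal(f$pos, 30L)
})

test_that("per-site and per-gene pi follow the closed form", {
  # single site, 10 alleles, alt count 5: 2 * 0.5 * 0.5 * 10/9
  counts <- make_counts("chr1", 5L, 10L, 5L, 10L, 0L)
  pi <- pi_per_gene(counts, one_gene(), "surface")
  expect_equal(pi$pi, 2 * 0.5 * 0.5 * 10 / 9, tolerance = 1e-12)

  # monomorphic gene: pi = 0
  expect_equal(pi_per_gene(counts, one_gene(), "cave")$pi, 0)

  # gene of 4 sites, one with pi = 0.5, three monomorphic -> mean 0.125
  # (n/(n-1) * 2pq = 0.5 needs 2pq = 0.45 at n = 10: p such that
  # 2p(1-p) = 0.45 -> p = 0.5 +- sqrt(0.1)/2; use allele counts directly)
  counts4 <- make_counts("chr1", c(10L, 20L, 30L, 40L),
                         n1 = 4L, alt1 = c(2L, 0L, 0L, 4L),
                         n2 = 4L, alt2 = 0L)
  # n=4, alt=2: 2 * .5 * .5 * 4/3 = 2/3; scale check instead with exact mean
  pi4 <- pi_per_gene(counts4, one_gene(), "surface")
  expect_equal(pi4$pi, (2 / 3) / 4, tolerance = 1e-12)
  expect_equal(pi4$n_sites, 4L)
})

test_that("genes with no retained sites carry NA, not zero", {
  counts <- make_counts("chr1", 5L, 10L, 5L, 10L, 2L)
  genes <- rbind(one_gene(id = "g1"),
                 one_gene(start = 2000L, end = 3000L, id = "empty"))
  stats <- per_gene_stats(counts, genes)
  expect_equal(stats$n_retained_sites, c(1L, 0L))
  expect_true(all(is.na(stats[2, c("pi_surface", "pi_cave", "fst", "dxy")])))
})

test_that("F_ST is 1 at fixed differences and <= 0 at equal frequencies", {
  fixed <- make_counts("chr1", 5L, 20L, 20L, 20L, 0L)
  expect_equal(fst_per_gene(fixed, one_gene())$fst, 1, tolerance = 1e-12)

  equal <- make_counts("chr1", 5L, 20L, 10L, 20L, 10L)
  expect_lte(fst_per_gene(equal, one_gene())$fst, 0)
})

test_that("per-site estimators agree with brute-force pair counting to 1e-10", {
  set.seed(31)
  n_sites <- 100L
  n1 <- 2L * sample(2:20, n_sites, replace = TRUE)
  n2 <- 2L * sample(2:20, n_sites, replace = TRUE)
  alt1 <- vapply(n1, function(n) sample(0:n, 1L), integer(1))
  alt2 <- vapply(n2, function(n) sample(0:n, 1L), integer(1))
  counts <- make_counts("chr1", 10L * seq_len(n_sites), n1, alt1, n2, alt2)
  genes <- data.frame(chrom = "chr1", start = 10L * seq_len(n_sites) - 5L,
                      end = 10L * seq_len(n_sites),
                      gene_id = sprintf("s%03d", seq_len(n_sites)))

  pi_hat <- pi_per_gene(counts, genes, "surface")$pi
  dxy_hat <- dxy_per_gene(counts, genes)$dxy
  fst_hat <- fst_per_gene(counts, genes)$fst
  for (i in seq_len(n_sites)) {
    expect_equal(pi_hat[i], brute_pi(n1[i], alt1[i]), tolerance = 1e-10)
    expect_equal(dxy_hat[i], brute_dxy(n1[i], alt1[i], n2[i], alt2[i]),
                 tolerance = 1e-10)
    theta <- brute_wc_theta(n1[i], alt1[i], n2[i], alt2[i])
    if (is.finite(theta) && !is.na(fst_hat[i])) {
      expect_equal(fst_hat[i], theta, tolerance = 1e-10)
    }
  }
})

test_that("D_XY is symmetric in the two populations and matches closed forms", {
  counts <- make_counts("chr1", c(5L, 15L, 25L),
                        n1 = 10L, alt1 = c(10L, 5L, 3L),
                        n2 = 10L, alt2 = c(0L, 5L, 8L))
  d <- dxy_per_gene(counts, one_gene())
  # mean of 1, 0.5, 0.62
  expect_equal(d$dxy, mean(c(1, 0.5, 0.3 * 0.2 + 0.8 * 0.7)),
               tolerance = 1e-12)

  swapped <- make_counts("chr1", c(5L, 15L, 25L),
                         n1 = 10L, alt1 = c(0L, 5L, 8L),
                         n2 = 10L, alt2 = c(10L, 5L, 3L))
  expect_identical(d$dxy, dxy_per_gene(swapped, one_gene())$dxy)
})

test_that("pi and D_XY stay in [0,1]; F_ST never exceeds 1", {
  cfg <- sim_config(seed = 13, n_genes = 30, sites_per_gene = 20,
                    background_F = 0.3, planted_F = 0.9,
                    planted_outlier_fraction = 0.2, geneset_size = 5)
  sim <- simulate_genotypes(cfg)
  pg <- per_gene_stats(filter_sites(allele_counts(sim),
                                    gene_annotation(sim$genes)),
                       gene_annotation(sim$genes))
  ok <- !is.na(pg$fst)
  expect_true(all(pg$pi_surface[ok] >= 0 & pg$pi_surface[ok] <= 1))
  expect_true(all(pg$dxy[ok] >= 0 & pg$dxy[ok] <= 1))
  expect_true(all(pg$fst[ok] <= 1))
})

test_that("permuting population labels drives mean F_ST to zero", {
  cfg <- sim_config(seed = 17, n_genes = 60, sites_per_gene = 30,
                    n_diploids_pop1 = 15, n_diploids_pop2 = 15,
                    background_F = 0.3, planted_outlier_fraction = 0,
                    missing_rate = 0, geneset_size = 5)
  sim <- simulate_genotypes(cfg)
  pooled <- cbind(sim$geno$surface, sim$geno$cave)
  set.seed(99)
  perm <- sample(ncol(pooled))
  geno <- list(surface = pooled[, perm[1:15]], cave = pooled[, perm[16:30]])
  pg <- per_gene_stats(allele_counts(geno, sites = sim$sites),
                       gene_annotation(sim$genes))
  expect_lt(abs(mean(pg$fst, na.rm = TRUE)), 0.02)
})
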