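# Brute-force oracles built from explicit allele vectors, independent of
# the frequency-based formulas in R/.

# allele vector of length n with `alt` ones
allele_vec <- function(n, alt) rep(c(1L, 0L), c(alt, n - alt))

# within-population diversity: fraction of differing unordered allele pairs
brute_pi <- function(n, alt) {
  a <- allele_vec(n, alt)
  pairs <- combn(n, 2L)
  mean(a[pairs[1L, ]] != a[pairs[2L, ]])
}

# between-population divergence: fraction of differing cross-population pairs
brute_dxy <- function(n1, alt1, n2, alt2) {
  a <- allele_vec(n1, alt1)
  b <- allele_vec(n2, alt2)
  mean(outer(a, b, `!=`))
}

# textbook Weir-Cockerham ANOVA on allele indicators: per-site numerator and
# denominator computed from explicit sums of squares over allele vectors
brute_wc <- function(n1, alt1, n2, alt2) {
  x <- list(allele_vec(n1, alt1), allele_vec(n2, alt2))
  n <- lengths(x)
  r <- 2L
  grand <- mean(unlist(x))
  ssb <- sum(n * (vapply(x, mean, 1) - grand)^2)
  ssw <- sum(vapply(x, function(v) sum((v - mean(v))^2), 1))
  msb <- ssb / (r - 1)
  msw <- ssw / (sum(n) - r)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  s2a <- (msb - msw) / nc
  list(num = s2a, den = s2a + msw / 1)  # theta = s2a / (s2a + s2w); s2w = msw
}

brute_wc_theta <- function(n1, alt1, n2, alt2) {
  wc <- brute_wc(n1, alt1, n2, alt2)
  wc$num / wc$den
}

# small helper: site_counts table from raw vectors
make_counts <- function(chrom, pos, n1, alt1, n2, alt2,
                        pops = c("surface", "cave")) {
  df <- data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  df[[paste0("n_", pops[1])]] <- n1
  df[[paste0("alt_", pops[1])]] <- alt1
  df[[paste0("n_", pops[2])]] <- n2
  df[[paste0("alt_", pops[2])]] <- alt2
  structure(df, populations = pops, class = c("site_counts", "data.frame"))
}

one_gene <- function(chrom = "chr1", start = 0L, end = 1000L, id = "g1") {
  data.frame(chrom = chrom, start = start, end = end, gene_id = id,
             stringsAsFactors = FALSE)
}
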