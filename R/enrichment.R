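#' Yates-corrected chi-square test for a 2x2 table
#'
#' The continuity-corrected chi-square statistic
#' `sum((|O - E| - 0.5)^2 / E)` over the four cells, with the correction
#' term clamped at zero whenever `|O - E| < 0.5`, and the p-value from
#' the chi-square distribution with 1 degree of freedom. This is the
#' statistic printed by standard 2x2 gene-set enrichment reports; an
#' exact (Fisher) p-value is available with `exact = TRUE`.
#'
#' @param table 2x2 matrix of non-negative counts, or a length-4 vector
#'   `c(a, b, c, d)` filled row-wise.
#' @param exact also compute Fisher's exact p-value.
#' @return list: `statistic`, `df` (= 1), `p_value`, and `p_exact` when
#'   requested. Zero row or column totals are an error.
#' @examples
#' # focal set 86/635 significant vs genome 1648/22710
#' yates_chi_square(c(86, 549, 1648, 21062))$statistic
#' @export
yates_chi_square <- function(table, exact = FALSE) {
  m <- as_2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("2x2 table has a zero row or column total", call. = FALSE)
  }
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  corr <- pmax(abs(m - e) - 0.5, 0)
  stat <- sum(corr^2 / e)
  out <- list(statistic = stat, df = 1L,
              p_value = pchisq(stat, df = 1L, lower.tail = FALSE))
  if (exact) out$p_exact <- stats::fisher.test(m)$p.value
  out
}

as_2x2 <- function(table) {
  m <- if (is.matrix(table)) table else matrix(table, nrow = 2L, byrow = TRUE)
  if (!all(dim(m) == 2L) || any(m < 0) || any(!is.finite(m))) {
    stop("expected a 2x2 table of non-negative counts", call. = FALSE)
  }
  m
}

#' Odds ratio with Woolf confidence interval
#'
#' The sample odds ratio `ad / bc` with a 95% confidence interval from
#' the Woolf construction: `log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c +
#' 1/d)`. When any cell is zero, the Haldane-Anscombe correction adds 0.5
#' to every cell before computing both the ratio and the interval.
#'
#' @inheritParams yates_chi_square
#' @param conf_level confidence level for the interval.
#' @return list: `or`, `ci_lower`, `ci_upper`, `corrected` (whether the
#'   +0.5 correction was applied).
#' @examples
#' odds_ratio(c(20, 5, 5, 20))$or  # ad/bc = 16
#' @export
odds_ratio <- function(table, conf_level = 0.95) {
  m <- as_2x2(table)
  corrected <- any(m == 0)
  if (corrected) m <- m + 0.5
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  se <- sqrt(sum(1 / m))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(or = or,
       ci_lower = exp(log(or) - z * se),
       ci_upper = exp(log(or) + z * se),
       corrected = corrected)
}

#' Kruskal-Wallis rank-sum test
#'
#' The rank-based H statistic with the standard tie correction
#' (`H / (1 - sum(t^3 - t) / (N^3 - N))` over tie groups of size `t`),
#' compared against the chi-square distribution with `groups - 1` degrees
#' of freedom. Used to compare per-gene divergence metric distributions
#' between gene groups, where normality cannot be assumed.
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @return list: `statistic`, `df`, `p_value`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))$statistic  # 3.857
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least two groups", call. = FALSE)
  }
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) == 0L)) {
    stop("every group must be non-empty", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  g <- rep.int(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(x)
  h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
  df <- length(groups) - 1L
  list(statistic = h, df = df,
       p_value = pchisq(h, df = df, lower.tail = FALSE))
}

#' Bootstrap resampling null for gene-set significance rates
#'
#' Asks whether the fraction of significant genes in a focal set is
#' extreme relative to random sets of genes: each of `n_boot` replicates
#' (default 9999) samples `sample_size` genes (default 500) without
#' replacement from the expression universe and records its percent
#' significant. The observed percent is then placed on that null as a
#' percentile, computed with strict inequality (replicates tied with the
#' observed value count as not-below, a conservative choice) and reported
#' as `"> 99.9"` when the observed value exceeds every replicate.
#'
#' @param gene_significance named logical vector over the whole expression
#'   universe (`TRUE` = significant), names = gene ids.
#' @param gene_set character vector of focal gene ids; must be a subset of
#'   the universe.
#' @param n_boot number of bootstrap replicates.
#' @param sample_size genes drawn per replicate (without replacement by
#'   default; `replace = TRUE` switches to with-replacement draws).
#' @param seed integer seed; results are bit-for-bit reproducible given
#'   the seed.
#' @param replace sample with replacement within each replicate.
#' @return An object of class `bootstrap_result`: `observed_percent`,
#'   `bootstrap_mean`, `ci95_halfwidth` (1.96 x SD of replicate
#'   percents), numeric `percentile` in \[0, 100\], its display
#'   `percentile_label`, plus the parameters and seed.
#' @examples
#' sig <- setNames(rep(c(TRUE, FALSE), c(20, 180)), paste0("g", 1:200))
#' bootstrap_expression_enrichment(sig, paste0("g", 1:15),
#'                                 n_boot = 99, sample_size = 50, seed = 1)
#' @export
bootstrap_expression_enrichment <- function(gene_significance, gene_set,
                                            n_boot = 9999L,
                                            sample_size = 500L,
                                            seed = 1L,
                                            replace = FALSE) {
  stopifnot(is.logical(gene_significance), !is.null(names(gene_significance)),
            n_boot >= 1L)
  if (length(gene_set) == 0L) stop("empty gene set", call. = FALSE)
  missing <- setdiff(gene_set, names(gene_significance))
  if (length(missing) > 0) {
    stop("gene set ids absent from the expression universe: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  if (!replace && sample_size > length(gene_significance)) {
    stop("sample_size exceeds the universe size", call. = FALSE)
  }
  observed <- 100 * mean(gene_significance[gene_set])
  set.seed(seed)
  sig <- unname(gene_significance)
  boot <- vapply(seq_len(n_boot), function(i) {
    100 * mean(sig[sample.int(length(sig), sample_size, replace = replace)])
  }, numeric(1))
  percentile <- 100 * sum(boot < observed) / n_boot
  structure(list(
    observed_percent = observed,
    n_set = length(gene_set),
    bootstrap_mean = mean(boot),
    ci95_halfwidth = 1.96 * sd(boot),
    percentile = percentile,
    percentile_label = if (all(boot < observed)) "> 99.9" else
      sprintf("%.1f", percentile),
    n_boot = as.integer(n_boot),
    sample_size = as.integer(sample_size),
    replace = replace,
    seed = as.integer(seed)
  ), class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "Bootstrap enrichment: observed %.1f%% significant (n = %d)\n",
    x$observed_percent, x$n_set))
  cat(sprintf("  null: %.1f +/- %.1f%% (%d samplings of %d genes, seed %d)\n",
              x$bootstrap_mean, x$ci95_halfwidth, x$n_boot, x$sample_size,
              x$seed))
  cat(sprintf("  percentile: %s\n", x$percentile_label))
  invisible(x)
}

#' Gene-set vs genome 2x2 enrichment
#'
#' Builds the 2x2 table comparing the significance rate inside a focal
#' gene set with the genome-wide rate and runs both
#' [yates_chi_square()] and [odds_ratio()] on it. Genes with no data
#' (absent from `calls`) are removed from both the set and the genome
#' counts. By default the genome row counts all genes including the set
#' (the construction that reproduces standard printed reports); set
#' `disjoint = TRUE` to compare the set against the non-set remainder
#' instead.
#'
#' @param calls data.frame with `gene_id` and a logical `significant`
#'   column (selection calls or outlier calls; for outlier tables pass
#'   `is_outlier` renamed or use `significant_col`).
#' @param gene_set character vector of gene ids.
#' @param significant_col name of the logical column to test.
#' @param disjoint compare the set against the genome excluding the set.
#' @return list: `table` (2x2 matrix), `chi_square`, `odds_ratio`,
#'   `set_rate`, `genome_rate`.
#' @export
set_vs_genome_enrichment <- function(calls, gene_set,
                                     significant_col = "significant",
                                     disjoint = FALSE) {
  stopifnot(significant_col %in% names(calls))
  sig <- calls[[significant_col]]
  in_set <- calls$gene_id %in% gene_set
  if (!any(in_set)) {
    stop("no gene-set member has data in the calls table", call. = FALSE)
  }
  genome <- if (disjoint) !in_set else rep(TRUE, nrow(calls))
  m <- matrix(c(sum(sig & in_set), sum(!sig & in_set),
                sum(sig & genome), sum(!sig & genome)),
              nrow = 2L, byrow = TRUE,
              dimnames = list(c("gene_set", "genome"),
                              c("significant", "not_significant")))
  list(table = m,
       chi_square = yates_chi_square(m),
       odds_ratio = odds_ratio(m),
       set_rate = m[1, 1] / sum(m[1, ]),
       genome_rate = m[2, 1] / sum(m[2, ]))
}
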