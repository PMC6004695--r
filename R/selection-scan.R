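#' Per-SNP p-values from a genome-wide normal fit
#'
#' Converts raw selection-scan statistics into p-values by fitting a
#' normal distribution genome wide: each statistic is standardized by the
#' genome-wide mean and standard deviation, and the p-value is the
#' standard normal's upper-tail probability at the resulting z-score
#' (one-sided, since larger scan statistics indicate stronger selection
#' signals; set `two_sided = TRUE` for the two-tailed alternative).
#'
#' @param stats data.frame with `chrom`, 1-based `pos` and the raw
#'   statistic `stat` (as written by [simulate_selection_stats()] or read
#'   from a scan's output with [read_tsv()]).
#' @param two_sided use the two-tailed probability instead.
#' @return The input with a `p` column appended, `p` in (0, 1).
#'   Degenerate input (fewer than 2 distinct values, so the fitted
#'   standard deviation is 0) is an error.
#' @examples
#' tab <- data.frame(chrom = "chr1", pos = 1:4, stat = c(0, 1, -1, 4))
#' fit_normal_pvalues(tab)$p
#' @export
fit_normal_pvalues <- function(stats, two_sided = FALSE) {
  stopifnot(all(c("chrom", "pos", "stat") %in% names(stats)))
  x <- stats$stat
  if (length(unique(x)) < 2L) {
    stop("degenerate statistic table: need at least 2 distinct values to fit ",
         "a genome-wide normal distribution", call. = FALSE)
  }
  z <- (x - mean(x)) / sd(x)
  p <- pnorm(z, lower.tail = FALSE)
  if (two_sided) p <- 2 * pmin(p, 1 - p)
  stats$p <- p
  stats
}

#' Per-gene selection calls from SNP-level p-values
#'
#' Assigns each SNP to every gene interval containing it, records the
#' minimum p-value per gene, and calls a gene significant when at least
#' one of its SNPs has p below `alpha`. Genes containing no SNPs are
#' treated as having no data and are absent from the output.
#'
#' @param pvalues data.frame with `chrom`, `pos`, `p` (see
#'   [fit_normal_pvalues()]).
#' @param annotation a [gene_annotation()] (or bare gene interval
#'   data.frame, 0-based half-open).
#' @param alpha significance level for the per-SNP p-values.
#' @return data.frame: `gene_id`, `n_snps`, `min_p`, `significant`.
#' @examples
#' genes <- data.frame(chrom = "chr1", start = 0, end = 100, gene_id = "g1")
#' snps <- data.frame(chrom = "chr1", pos = c(10, 50), p = c(0.2, 0.04))
#' gene_selection_calls(snps, genes)
#' @export
gene_selection_calls <- function(pvalues, annotation, alpha = 0.05) {
  stopifnot(all(c("chrom", "pos", "p") %in% names(pvalues)))
  genes <- as_gene_table(annotation)
  hits <- site_gene_hits(pvalues, genes)
  if (length(hits$site) == 0L) {
    return(data.frame(gene_id = character(), n_snps = integer(),
                      min_p = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  min_p <- tapply(pvalues$p[hits$site], hits$gene, min)
  n_snps <- tapply(hits$site, hits$gene, length)
  idx <- as.integer(names(min_p))
  out <- data.frame(gene_id = genes$gene_id[idx],
                    n_snps = as.integer(n_snps),
                    min_p = as.numeric(min_p),
                    stringsAsFactors = FALSE)
  out$significant <- out$min_p < alpha
  out[order(idx), , drop = FALSE]
}
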