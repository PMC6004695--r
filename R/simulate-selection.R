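#' Simulate a per-SNP selection-scan statistic table
#'
#' Emulates the output of an external haplotype-based selection scan:
#' genome-wide the raw statistic is standard normal, while inside each
#' planted gene a configurable number of SNPs receive a positive location
#' shift (`config$selection_shift`, in null standard deviations). The
#' table is what [fit_normal_pvalues()] and [gene_selection_calls()]
#' consume; the scan model itself is treated as an external black box
#' throughout the package.
#'
#' @param config a [sim_config()].
#' @param truth per-gene truth data.frame with `gene_id` and `planted`
#'   (as returned in `simulate_genotypes(config)$truth`). An empty or
#'   all-`FALSE` truth yields a pure-null table.
#' @param genes gene intervals (`chrom`, `start`, `end`, `gene_id`,
#'   0-based half-open). Defaults to the same layout
#'   [simulate_genotypes()] uses, so coordinates line up across stages.
#' @return A `selection_stats` data.frame: `chrom`, 1-based `pos`,
#'   `stat`. SNPs are placed inside the gene intervals.
#' @examples
#' cfg <- sim_config(seed = 3, n_genes = 10, sites_per_gene = 10)
#' truth <- simulate_genotypes(cfg)$truth
#' head(simulate_selection_stats(cfg, truth))
#' @export
simulate_selection_stats <- function(config, truth, genes = default_gene_layout(config)) {
  validate_sim_config(config)
  stopifnot(all(c("gene_id", "planted") %in% names(truth)))
  set.seed(config$seed + 1L)

  k <- config$snps_per_gene
  genes <- genes[match(truth$gene_id, genes$gene_id), , drop = FALSE]
  n_genes <- nrow(genes)
  if (k == 0L || n_genes == 0L) {
    return(structure(data.frame(chrom = character(), pos = integer(),
                                stat = numeric(), stringsAsFactors = FALSE),
                     class = c("selection_stats", "data.frame")))
  }
  # spread k SNPs evenly inside each gene interval
  width <- genes$end - genes$start
  offs <- vapply(seq_len(k), function(i) ceiling(width * i / (k + 1L)), numeric(n_genes))
  if (n_genes == 1L) offs <- matrix(offs, nrow = 1L)
  pos <- as.integer(t(offs) + rep(genes$start, each = k))  # 1-based: start0 + off
  stat <- rnorm(n_genes * k)
  shifted <- rep(truth$planted, each = k) &
    rep(seq_len(k), n_genes) <= config$n_shifted_snps
  stat[shifted] <- stat[shifted] + config$selection_shift

  structure(data.frame(chrom = rep(genes$chrom, each = k), pos = pos,
                       stat = stat, stringsAsFactors = FALSE),
            class = c("selection_stats", "data.frame"))
}

# gene layout matching simulate_genotypes(): head-to-tail on chr1,
# sites every 10 bp, 100 bp intergenic gaps
default_gene_layout <- function(config) {
  gene_span <- config$sites_per_gene * 10L + 10L
  start0 <- (seq_len(config$n_genes) - 1L) * (gene_span + 100L)
  data.frame(chrom = "chr1", start = start0, end = start0 + gene_span,
             gene_id = sprintf("gene%04d", seq_len(config$n_genes)),
             stringsAsFactors = FALSE)
}
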