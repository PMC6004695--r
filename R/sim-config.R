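#' Simulation configuration
#'
#' Bundles every tunable of the synthetic two-population study: genotype
#' divergence (Balding-Nichols background and planted F), per-SNP selection
#' statistics, differential-expression (DE) tables for fish paralogs and
#' human genes, the ortholog map, and a focal gene set with a planted
#' enrichment. The defaults describe the emulated study design: 10 + 9
#' diploids, genome-wide background differentiation of 0.2, a 5% fraction
#' of strongly diverged genes, roughly half of genes differentially
#' expressed, a cross-species direction-concordance rate of 0.6, and a
#' 500-gene focal set with a 1.3-fold boosted DE probability.
#'
#' @param seed integer seed; the single PRNG stream for a run is derived
#'   from it (recorded in all outputs).
#' @param n_genes number of genes (also the number of human genes in the
#'   DE simulation; each maps to 1-2 fish paralogs).
#' @param sites_per_gene biallelic sites simulated per gene.
#' @param n_diploids_pop1,n_diploids_pop2 diploid sample sizes for the
#'   "surface"-like and "cave"-like populations.
#' @param background_F Balding-Nichols divergence parameter in (0,1) for
#'   ordinary genes.
#' @param planted_outlier_fraction proportion of genes planted as
#'   divergence outliers.
#' @param planted_F divergence parameter for planted genes; must exceed
#'   `background_F` whenever outliers are planted.
#' @param missing_rate per-genotype missingness probability.
#' @param snps_per_gene number of selection-scan SNP statistics per gene.
#' @param n_shifted_snps number of shifted SNPs within each planted gene.
#' @param selection_shift positive location shift of the selection
#'   statistic at shifted SNPs, in null standard deviations.
#' @param de_fraction proportion of truly differentially expressed genes.
#' @param de_effect absolute log2 fold-change for DE genes.
#' @param concordance_rate probability that a DE fish paralog shifts in the
#'   same direction as its human ortholog.
#' @param geneset_size size of the focal gene set.
#' @param geneset_enrichment multiplier on the DE probability inside the
#'   focal set (1 = no enrichment).
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 20, sites_per_gene = 10)
#' cfg$background_F
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       sites_per_gene = 50L,
                       n_diploids_pop1 = 10L,
                       n_diploids_pop2 = 9L,
                       background_F = 0.2,
                       planted_outlier_fraction = 0.05,
                       planted_F = 0.6,
                       missing_rate = 0.1,
                       snps_per_gene = 5L,
                       n_shifted_snps = 3L,
                       selection_shift = 5,
                       de_fraction = 0.5,
                       de_effect = 1,
                       concordance_rate = 0.6,
                       geneset_size = 500L,
                       geneset_enrichment = 1.3) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    sites_per_gene = as.integer(sites_per_gene),
    n_diploids_pop1 = as.integer(n_diploids_pop1),
    n_diploids_pop2 = as.integer(n_diploids_pop2),
    background_F = background_F,
    planted_outlier_fraction = planted_outlier_fraction,
    planted_F = planted_F,
    missing_rate = missing_rate,
    snps_per_gene = as.integer(snps_per_gene),
    n_shifted_snps = as.integer(n_shifted_snps),
    selection_shift = selection_shift,
    de_fraction = de_fraction,
    de_effect = de_effect,
    concordance_rate = concordance_rate,
    geneset_size = as.integer(geneset_size),
    geneset_enrichment = geneset_enrichment
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$seed) == 1L, !is.na(cfg$seed),
    cfg$n_genes >= 1L, cfg$sites_per_gene >= 1L,
    cfg$n_diploids_pop1 >= 1L, cfg$n_diploids_pop2 >= 1L,
    cfg$snps_per_gene >= 0L,
    cfg$n_shifted_snps >= 0L, cfg$n_shifted_snps <= cfg$snps_per_gene
  )
  for (p in c("planted_outlier_fraction", "missing_rate", "de_fraction",
              "concordance_rate")) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop(sprintf("`%s` must be a proportion in [0, 1]", p), call. = FALSE)
    }
  }
  for (p in c("background_F", "planted_F")) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      stop(sprintf(paste0("`%s` must lie strictly inside (0, 1); the fixed ",
                          "limits are degenerate for the Balding-Nichols model"),
                   p),
           call. = FALSE)
    }
  }
  if (cfg$planted_outlier_fraction > 0 && cfg$planted_F <= cfg$background_F) {
    stop("`planted_F` must exceed `background_F` when outliers are planted",
         call. = FALSE)
  }
  if (cfg$geneset_size > cfg$n_genes) {
    stop("`geneset_size` cannot exceed `n_genes`", call. = FALSE)
  }
  if (cfg$de_effect < 0 || cfg$selection_shift < 0 || cfg$geneset_enrichment < 0) {
    stop("effect-size parameters must be non-negative", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Two-population simulation configuration\n")
  cat(sprintf("  seed %d; %d genes x %d sites; diploids %d + %d\n",
              x$seed, x$n_genes, x$sites_per_gene,
              x$n_diploids_pop1, x$n_diploids_pop2))
  cat(sprintf("  F: background %.3g, planted %.3g (fraction %.3g); missing %.3g\n",
              x$background_F, x$planted_F, x$planted_outlier_fraction,
              x$missing_rate))
  cat(sprintf("  selection: %d SNPs/gene, %d shifted by %.3g SD in planted genes\n",
              x$snps_per_gene, x$n_shifted_snps, x$selection_shift))
  cat(sprintf("  DE: fraction %.3g, |log2FC| %.3g, concordance %.3g\n",
              x$de_fraction, x$de_effect, x$concordance_rate))
  cat(sprintf("  gene set: %d genes, enrichment x%.3g\n",
              x$geneset_size, x$geneset_enrichment))
  invisible(x)
}
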