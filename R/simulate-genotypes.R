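#' Simulate two-population genotypes under the Balding-Nichols model
#'
#' Draws, for every gene, an ancestral allele frequency uniform on
#' \[0.05, 0.95\] (bounded away from the boundaries so that sites
#' monomorphic in both populations do not dominate), then for every site in
#' the gene draws each population's allele frequency from a Beta
#' distribution with mean equal to the ancestral frequency and shape
#' parameters `p(1-F)/F` and `(1-p)(1-F)/F`. `F` is `background_F` for
#' ordinary genes and `planted_F` for the planted divergence outliers, so
#' the expected Weir-Cockerham F_ST of a gene equals its `F`. Diploid
#' genotypes are binomial draws from the population frequency; genotypes
#' are then set to missing independently at `missing_rate`.
#'
#' Genes are laid out head-to-tail on a single chromosome with sites every
#' 10 bp, so interval-based filtering and ranking downstream see realistic
#' coordinates.
#'
#' @param config a [sim_config()].
#' @return An object of class `genotype_sim`: a list with
#'   \describe{
#'     \item{geno}{named list of two integer matrices (sites x diploids,
#'       dosages 0/1/2, `NA` = missing), one per population.}
#'     \item{sites}{data.frame of site coordinates (`chrom`, 1-based
#'       `pos`, `gene_id`).}
#'     \item{genes}{data.frame of gene intervals (`chrom`, `start`, `end`,
#'       `gene_id`; 0-based half-open, BED convention).}
#'     \item{truth}{data.frame per gene: `gene_id`, `planted` flag, the
#'       divergence parameter `F`, ancestral frequency `p_anc`.}
#'     \item{config}{the configuration, seed included.}
#'   }
#' @examples
#' sim <- simulate_genotypes(sim_config(seed = 7, n_genes = 5,
#'                                      sites_per_gene = 4))
#' dim(sim$geno$surface)
#' table(sim$truth$planted)
#' @seealso [allele_counts()], [write_sim_vcf()]
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)

  n_genes <- config$n_genes
  spg <- config$sites_per_gene
  n1 <- config$n_diploids_pop1
  n2 <- config$n_diploids_pop2
  n_sites <- n_genes * spg

  gene_id <- sprintf("gene%04d", seq_len(n_genes))
  n_planted <- floor(config$planted_outlier_fraction * n_genes)
  planted <- rep(FALSE, n_genes)
  if (n_planted > 0) planted[sample.int(n_genes, n_planted)] <- TRUE
  F_gene <- ifelse(planted, config$planted_F, config$background_F)
  p_anc <- runif(n_genes, 0.05, 0.95)

  # 10 bp between sites, 100 bp between genes
  gene_span <- spg * 10L + 10L
  gene_start0 <- (seq_len(n_genes) - 1L) * (gene_span + 100L)
  genes <- data.frame(
    chrom = "chr1", start = gene_start0, end = gene_start0 + gene_span,
    gene_id = gene_id, stringsAsFactors = FALSE
  )
  pos <- rep(gene_start0, each = spg) + 10L * rep(seq_len(spg), n_genes)
  sites <- data.frame(
    chrom = "chr1", pos = pos, gene_id = rep(gene_id, each = spg),
    stringsAsFactors = FALSE
  )

  p_site <- rep(p_anc, each = spg)
  F_site <- rep(F_gene, each = spg)
  shape1 <- p_site * (1 - F_site) / F_site
  shape2 <- (1 - p_site) * (1 - F_site) / F_site
  p1 <- rbeta(n_sites, shape1, shape2)
  p2 <- rbeta(n_sites, shape1, shape2)

  draw_pop <- function(p, n_dip) {
    g <- matrix(rbinom(length(p) * n_dip, 2L, rep(p, n_dip)),
                nrow = length(p), ncol = n_dip)
    if (config$missing_rate > 0) {
      g[runif(length(g)) < config$missing_rate] <- NA_integer_
    }
    g
  }
  geno <- list(surface = draw_pop(p1, n1), cave = draw_pop(p2, n2))
  colnames(geno$surface) <- sprintf("surface_%02d", seq_len(n1))
  colnames(geno$cave) <- sprintf("cave_%02d", seq_len(n2))

  structure(list(
    geno = geno, sites = sites, genes = genes,
    truth = data.frame(gene_id = gene_id, planted = planted, F = F_gene,
                       p_anc = p_anc, stringsAsFactors = FALSE),
    config = config
  ), class = "genotype_sim")
}

#' @export
print.genotype_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated genotypes: %d sites in %d genes; %d + %d diploids; %d planted outlier gene(s)\n",
    nrow(x$sites), nrow(x$genes), ncol(x$geno[[1]]), ncol(x$geno[[2]]),
    sum(x$truth$planted)))
  invisible(x)
}

#' Per-population allele counts from simulated or parsed genotypes
#'
#' Collapses diploid genotype dosages to the per-site, per-population
#' summary all downstream estimators use: the number of successfully
#' genotyped allele copies `n` (twice the non-missing individuals) and the
#' alternate-allele count.
#'
#' @param x a `genotype_sim` object, or a named list of two dosage
#'   matrices (sites x individuals, values 0/1/2/`NA`) together with
#'   `sites`.
#' @param sites data.frame with `chrom` and 1-based `pos` (taken from `x`
#'   when `x` is a `genotype_sim`).
#' @return A `site_counts` data.frame: `chrom`, `pos`, and for each
#'   population `n_<pop>` and `alt_<pop>`; population labels are stored in
#'   `attr(, "populations")`.
#' @examples
#' sim <- simulate_genotypes(sim_config(seed = 1, n_genes = 2,
#'                                      sites_per_gene = 3))
#' allele_counts(sim)
#' @export
allele_counts <- function(x, sites = NULL) {
  if (inherits(x, "genotype_sim")) {
    geno <- x$geno
    sites <- x$sites[, c("chrom", "pos")]
  } else {
    geno <- x
    stopifnot(!is.null(sites))
  }
  stopifnot(length(geno) == 2L, !is.null(names(geno)))
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    stringsAsFactors = FALSE)
  for (pop in names(geno)) {
    g <- geno[[pop]]
    out[[paste0("n_", pop)]] <- 2L * rowSums(!is.na(g))
    out[[paste0("alt_", pop)]] <- rowSums(g, na.rm = TRUE)
  }
  structure(out, populations = names(geno), class = c("site_counts",
                                                      "data.frame"))
}
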