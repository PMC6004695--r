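#' Filter biallelic sites before per-gene estimation
#'
#' Applies, in order, the three site filters used throughout the
#' divergence analysis:
#' \enumerate{
#'   \item drop sites inside repeat-masked intervals (overlapping masks
#'     are merged first);
#'   \item drop indel-affected bases and every base within `indel_flank`
#'     (default 10) bp of them;
#'   \item drop sites where either population has fewer than
#'     `min_individuals` (default 6) successfully genotyped individuals.
#' }
#'
#' @param counts a `site_counts` data.frame (see [allele_counts()]).
#' @param annotation a [gene_annotation()] carrying masks and indels.
#' @param min_individuals minimum non-missing diploid individuals required
#'   in each population.
#' @param indel_flank bases excluded on each side of an indel-affected
#'   span.
#' @return The retained `site_counts` subset, with a `filter_log`
#'   attribute counting sites removed by each rule. Mask or indel
#'   intervals on chromosomes absent from the dataset trigger a warning
#'   and are ignored.
#' @examples
#' sim <- simulate_genotypes(sim_config(seed = 1, n_genes = 3,
#'                                      sites_per_gene = 5))
#' ann <- gene_annotation(sim$genes)
#' filtered <- filter_sites(allele_counts(sim), ann)
#' attr(filtered, "filter_log")
#' @export
filter_sites <- function(counts, annotation, min_individuals = 6L,
                         indel_flank = 10L) {
  stopifnot(inherits(annotation, "gene_annotation"))
  pops <- attr(counts, "populations")
  log <- c(masked = 0L, near_indel = 0L, low_coverage = 0L)

  warn_unknown <- function(df, what) {
    unknown <- setdiff(unique(df$chrom), unique(counts$chrom))
    if (length(unknown) > 0) {
      warning(sprintf("%s intervals on unknown chromosome(s) %s ignored",
                      what, paste(unknown, collapse = ", ")), call. = FALSE)
      df <- df[!df$chrom %in% unknown, , drop = FALSE]
    }
    df
  }

  keep <- rep(TRUE, nrow(counts))
  site_gr <- sites_to_granges(counts$chrom, counts$pos)

  masks <- warn_unknown(annotation$masks, "mask")
  if (nrow(masks) > 0) {
    mask_gr <- GenomicRanges::reduce(intervals_to_granges(masks))
    hit <- IRanges::overlapsAny(site_gr, mask_gr)
    log["masked"] <- sum(hit & keep)
    keep <- keep & !hit
  }

  indels <- warn_unknown(annotation$indels, "indel")
  if (nrow(indels) > 0) {
    flank <- indels
    flank$start <- pmax(0L, flank$start - indel_flank)
    flank$end <- flank$end + indel_flank
    hit <- IRanges::overlapsAny(site_gr, intervals_to_granges(flank))
    log["near_indel"] <- sum(hit & keep)
    keep <- keep & !hit
  }

  n_cols <- paste0("n_", pops)
  covered <- counts[[n_cols[1]]] >= 2L * min_individuals &
    counts[[n_cols[2]]] >= 2L * min_individuals
  log["low_coverage"] <- sum(keep & !covered)
  keep <- keep & covered

  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "populations") <- pops
  attr(out, "filter_log") <- log
  class(out) <- c("site_counts", "data.frame")
  out
}

# indices of retained sites per gene; sites in overlapping genes count for
# every overlapping gene
site_gene_hits <- function(counts, genes) {
  hits <- GenomicRanges::findOverlaps(
    sites_to_granges(counts$chrom, counts$pos), intervals_to_granges(genes))
  list(site = S4Vectors::queryHits(hits), gene = S4Vectors::subjectHits(hits))
}

pop_cols <- function(counts, population) {
  pops <- attr(counts, "populations")
  if (!population %in% pops) {
    stop(sprintf("unknown population '%s' (dataset has: %s)", population,
                 paste(pops, collapse = ", ")), call. = FALSE)
  }
  list(n = counts[[paste0("n_", population)]],
       alt = counts[[paste0("alt_", population)]])
}

# per-site nucleotide diversity: 2 p (1-p) n / (n-1), NA where n < 2
site_pi <- function(n, alt) {
  p <- alt / n
  out <- 2 * p * (1 - p) * n / (n - 1)
  out[n < 2L] <- NA_real_
  out
}

mean_by_gene <- function(values, hits, n_genes) {
  ok <- !is.na(values[hits$site])
  sums <- rowsum_safe(values[hits$site][ok], hits$gene[ok], n_genes)
  n <- rowsum_safe(rep(1, sum(ok)), hits$gene[ok], n_genes)
  ifelse(n > 0, sums / n, NA_real_)
}

rowsum_safe <- function(x, group, n_groups) {
  out <- numeric(n_groups)
  if (length(x) > 0) {
    s <- rowsum(x, group)
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

#' Per-gene nucleotide diversity (pi)
#'
#' Per-site pi is `2 p (1 - p) n / (n - 1)`, the unbiased expected
#' heterozygosity with `p` the sample alternate-allele frequency and `n`
#' the non-missing allele count in the chosen population; sites with
#' `n < 2` are skipped. The per-gene value is the mean of per-site pi over
#' retained sites inside the gene interval, so genes of different lengths
#' stay comparable under genome-wide ranking. Genes with no retained
#' sites get `NA`, not zero.
#'
#' @param counts a (filtered) `site_counts` data.frame.
#' @param annotation a [gene_annotation()] (or a bare gene data.frame).
#' @param population which population's diversity to compute (one of the
#'   labels in `attr(counts, "populations")`).
#' @return data.frame: `gene_id`, `n_sites`, `pi`.
#' @examples
#' counts <- structure(
#'   data.frame(chrom = "chr1", pos = 5L, n_surface = 10L, alt_surface = 5L,
#'              n_cave = 10L, alt_cave = 0L),
#'   populations = c("surface", "cave"), class = c("site_counts", "data.frame"))
#' genes <- data.frame(chrom = "chr1", start = 0, end = 10, gene_id = "g1")
#' pi_per_gene(counts, genes, "surface")$pi  # 2 * .25 * 10/9 = 0.5556
#' @export
pi_per_gene <- function(counts, annotation, population) {
  genes <- as_gene_table(annotation)
  pc <- pop_cols(counts, population)
  hits <- site_gene_hits(counts, genes)
  values <- site_pi(pc$n, pc$alt)
  data.frame(gene_id = genes$gene_id,
             n_sites = gene_site_counts(values, hits, nrow(genes)),
             pi = mean_by_gene(values, hits, nrow(genes)),
             stringsAsFactors = FALSE)
}

gene_site_counts <- function(values, hits, n_genes) {
  ok <- !is.na(values[hits$site])
  as.integer(rowsum_safe(rep(1, sum(ok)), hits$gene[ok], n_genes))
}

as_gene_table <- function(annotation) {
  if (inherits(annotation, "gene_annotation")) annotation$genes else annotation
}

# Weir-Cockerham variance components from per-population allele counts
# (random-union-of-gametes form; n1, n2 in allele copies). Returns the
# per-site numerator and denominator of the ratio-of-sums estimator.
wc_components <- function(n1, alt1, n2, alt2) {
  p1 <- alt1 / n1
  p2 <- alt2 / n2
  nt <- n1 + n2
  pbar <- (alt1 + alt2) / nt
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nt - 2)
  nc <- nt - (n1^2 + n2^2) / nt
  num <- msp - msg
  den <- msp + (nc - 1) * msg
  bad <- n1 < 2L | n2 < 2L
  num[bad] <- NA_real_
  den[bad] <- NA_real_
  list(num = num, den = den)
}

#' Per-gene Weir-Cockerham F_ST
#'
#' Computes the Weir-Cockerham variance-component estimator per site from
#' the two populations' allele counts, then aggregates each gene as the
#' ratio of summed numerator components to summed denominator components
#' over its retained sites (the "weighted", ratio-of-sums multi-site
#' form). The alternative mean-of-per-site-ratios form is available via
#' `method = "mean"`; it is unstable for low-diversity sites and not the
#' default. Estimates are not clamped: slightly negative values are
#' legitimate draws of the estimator and keep the genome-wide ranking
#' monotone.
#'
#' Sites monomorphic in both populations contribute zero to both sums;
#' genes whose denominator sum is zero (no polymorphic retained site) get
#' `NA`.
#'
#' @inheritParams pi_per_gene
#' @param method `"weighted"` (ratio of sums, default) or `"mean"`
#'   (mean of per-site ratios over polymorphic sites).
#' @return data.frame: `gene_id`, `n_sites`, `fst`.
#' @examples
#' # fixed difference: per-site F_ST = 1
#' counts <- structure(
#'   data.frame(chrom = "chr1", pos = 5L, n_surface = 20L, alt_surface = 20L,
#'              n_cave = 20L, alt_cave = 0L),
#'   populations = c("surface", "cave"), class = c("site_counts", "data.frame"))
#' genes <- data.frame(chrom = "chr1", start = 0, end = 10, gene_id = "g1")
#' fst_per_gene(counts, genes)$fst
#' @export
fst_per_gene <- function(counts, annotation, method = c("weighted", "mean")) {
  method <- match.arg(method)
  genes <- as_gene_table(annotation)
  pops <- attr(counts, "populations")
  pc1 <- pop_cols(counts, pops[1]); pc2 <- pop_cols(counts, pops[2])
  wc <- wc_components(pc1$n, pc1$alt, pc2$n, pc2$alt)
  hits <- site_gene_hits(counts, genes)
  n_genes <- nrow(genes)
  if (method == "weighted") {
    usable <- !is.na(wc$den)
    ok <- usable[hits$site]
    num <- rowsum_safe(wc$num[hits$site][ok], hits$gene[ok], n_genes)
    den <- rowsum_safe(wc$den[hits$site][ok], hits$gene[ok], n_genes)
    fst <- ifelse(den > 0, num / den, NA_real_)
  } else {
    ratio <- ifelse(!is.na(wc$den) & wc$den != 0, wc$num / wc$den, NA_real_)
    fst <- mean_by_gene(ratio, hits, n_genes)
  }
  data.frame(gene_id = genes$gene_id,
             n_sites = gene_site_counts(wc$den, hits, n_genes),
             fst = fst, stringsAsFactors = FALSE)
}

#' Per-gene absolute divergence (D_XY)
#'
#' Per-site divergence is `p1 (1 - p2) + p2 (1 - p1)` with `p1`, `p2` the
#' two populations' alternate-allele frequencies -- the probability that
#' one allele drawn from each population differs. The per-gene value is
#' the mean over retained sites; the measure is exactly symmetric in the
#' two populations, and genes with no retained sites get `NA`.
#'
#' @inheritParams pi_per_gene
#' @return data.frame: `gene_id`, `n_sites`, `dxy`.
#' @examples
#' counts <- structure(
#'   data.frame(chrom = "chr1", pos = 5L, n_surface = 10L, alt_surface = 3L,
#'              n_cave = 10L, alt_cave = 8L),
#'   populations = c("surface", "cave"), class = c("site_counts", "data.frame"))
#' genes <- data.frame(chrom = "chr1", start = 0, end = 10, gene_id = "g1")
#' dxy_per_gene(counts, genes)$dxy  # 0.3*0.2 + 0.8*0.7 = 0.62
#' @export
dxy_per_gene <- function(counts, annotation) {
  genes <- as_gene_table(annotation)
  pops <- attr(counts, "populations")
  pc1 <- pop_cols(counts, pops[1]); pc2 <- pop_cols(counts, pops[2])
  p1 <- pc1$alt / pc1$n
  p2 <- pc2$alt / pc2$n
  d <- p1 * (1 - p2) + p2 * (1 - p1)
  d[pc1$n < 1L | pc2$n < 1L] <- NA_real_
  hits <- site_gene_hits(counts, genes)
  data.frame(gene_id = genes$gene_id,
             n_sites = gene_site_counts(d, hits, nrow(genes)),
             dxy = mean_by_gene(d, hits, nrow(genes)),
             stringsAsFactors = FALSE)
}

#' All per-gene divergence statistics in one table
#'
#' Convenience wrapper joining [pi_per_gene()] for both populations,
#' [fst_per_gene()] and [dxy_per_gene()] on the filtered dataset.
#'
#' @inheritParams fst_per_gene
#' @return data.frame: `gene_id`, `chrom`, `start`, `end`,
#'   `n_retained_sites`, `pi_<pop1>`, `pi_<pop2>`, `fst`, `dxy`. Genes
#'   with no retained sites carry `NA` in every statistic.
#' @export
per_gene_stats <- function(counts, annotation, method = "weighted") {
  genes <- as_gene_table(annotation)
  pops <- attr(counts, "populations")
  pi1 <- pi_per_gene(counts, genes, pops[1])
  pi2 <- pi_per_gene(counts, genes, pops[2])
  fst <- fst_per_gene(counts, genes, method = method)
  dxy <- dxy_per_gene(counts, genes)
  out <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom, start = genes$start,
    end = genes$end, n_retained_sites = dxy$n_sites,
    pi1 = pi1$pi, pi2 = pi2$pi, fst = fst$fst, dxy = dxy$dxy,
    stringsAsFactors = FALSE
  )
  names(out)[names(out) == "pi1"] <- paste0("pi_", pops[1])
  names(out)[names(out) == "pi2"] <- paste0("pi_", pops[2])
  out
}
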