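#' Pipeline configuration
#'
#' Collects every input path and parameter of the end-to-end analysis:
#' genotypes (VCF), gene/mask/indel intervals (BED), the sample-to-
#' population map, the per-SNP selection-statistic table, the fish and
#' human DE tables, the ortholog map, and the two focal gene-set lists
#' (one in the genomic gene namespace for selection enrichment, one in
#' the expression namespace for the bootstrap null). All thresholds
#' default to the study values: top 5% F_ST, top 20% D_XY, alpha 0.05,
#' 500-gene pi exclusion, 9999 bootstrap samplings of 500 genes.
#'
#' @param vcf,genes_bed,populations_tsv,stats_tsv,fish_de_tsv,human_de_tsv,ortholog_map_tsv,geneset_genomic,geneset_expression
#'   input file paths (see the vignette for the formats). `masks_bed` and
#'   `indels_bed` are optional.
#' @param masks_bed,indels_bed optional BED paths.
#' @param out_dir output directory (created if absent).
#' @param thresholds an [outlier_thresholds()].
#' @param min_individuals site filter: minimum genotyped individuals per
#'   population.
#' @param alpha significance level for selection calls and DE calls.
#' @param n_boot,sample_size bootstrap parameters.
#' @param seed integer seed recorded in every output.
#' @return A `pipeline_config` list; missing input paths are an error
#'   naming the offending field.
#' @export
pipeline_config <- function(vcf, genes_bed, populations_tsv, stats_tsv,
                            fish_de_tsv, human_de_tsv, ortholog_map_tsv,
                            geneset_genomic, geneset_expression,
                            out_dir,
                            masks_bed = NULL, indels_bed = NULL,
                            thresholds = outlier_thresholds(),
                            min_individuals = 6L,
                            alpha = 0.05,
                            n_boot = 9999L, sample_size = 500L,
                            seed = 1L) {
  cfg <- list(vcf = vcf, genes_bed = genes_bed,
              populations_tsv = populations_tsv, stats_tsv = stats_tsv,
              fish_de_tsv = fish_de_tsv, human_de_tsv = human_de_tsv,
              ortholog_map_tsv = ortholog_map_tsv,
              geneset_genomic = geneset_genomic,
              geneset_expression = geneset_expression,
              masks_bed = masks_bed, indels_bed = indels_bed,
              out_dir = out_dir, thresholds = thresholds,
              min_individuals = as.integer(min_individuals),
              alpha = alpha, n_boot = as.integer(n_boot),
              sample_size = as.integer(sample_size),
              seed = as.integer(seed))
  required <- c("vcf", "genes_bed", "populations_tsv", "stats_tsv",
                "fish_de_tsv", "human_de_tsv", "ortholog_map_tsv",
                "geneset_genomic", "geneset_expression")
  for (field in c(required, "masks_bed", "indels_bed")) {
    path <- cfg[[field]]
    if (is.null(path)) {
      if (field %in% required) stop("missing input path: ", field, call. = FALSE)
      next
    }
    if (!file.exists(path)) {
      stop(sprintf("input file for `%s` not found: %s", field, path),
           call. = FALSE)
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full divergence/enrichment/concordance pipeline
#'
#' Executes the stages in order -- site filtering, per-gene pi/F_ST/D_XY,
#' selection calls from the statistic table, multi-metric outlier
#' classification, gene-set enrichment (2x2 chi-square, odds ratio,
#' Kruskal-Wallis outlier-vs-set comparisons, bootstrap null), and
#' cross-species direction concordance -- writing each stage's TSV plus a
#' YAML manifest (inputs, parameters, seed, completed stages) to
#' `config$out_dir`. Stage failures propagate with a stage-tagged message
#' after the manifest of completed stages is written.
#'
#' @param config a [pipeline_config()].
#' @return A `pipeline_report` list with every stage's result.
#' @seealso [write_sim_inputs()] to materialize a fully synthetic input
#'   bundle for the pipeline.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  completed <- character()
  report <- list(config = config)

  run_stage <- function(name, expr) {
    result <- tryCatch(expr, error = function(e) {
      write_manifest(config, completed, failed = name)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    completed <<- c(completed, name)
    result
  }
  out_path <- function(name) file.path(config$out_dir, name)

  report$counts <- run_stage("read_genotypes", {
    pops_df <- read_tsv(config$populations_tsv)
    pops <- split(pops_df$sample, pops_df$population)
    pops <- pops[unique(pops_df$population)]  # keep file order
    read_vcf_counts(config$vcf, pops)
  })

  annotation <- run_stage("annotation", {
    gene_annotation(
      genes = read_bed(config$genes_bed),
      masks = if (!is.null(config$masks_bed)) read_bed(config$masks_bed),
      indels = if (!is.null(config$indels_bed)) read_bed(config$indels_bed))
  })

  filtered <- run_stage("filter_sites", {
    f <- filter_sites(report$counts, annotation,
                      min_individuals = config$min_individuals)
    log <- attr(f, "filter_log")
    write_tsv(data.frame(rule = names(log), n_removed = as.integer(log)),
              out_path("filter_log.tsv"))
    f
  })
  report$filter_log <- attr(filtered, "filter_log")

  report$per_gene <- run_stage("per_gene_stats", {
    stats <- per_gene_stats(filtered, annotation)
    write_tsv(stats, out_path("per_gene_stats.tsv"))
    stats
  })

  report$selection <- run_stage("selection_calls", {
    raw <- read_tsv(config$stats_tsv)
    calls <- gene_selection_calls(fit_normal_pvalues(raw), annotation,
                                  alpha = config$alpha)
    write_tsv(calls, out_path("selection_calls.tsv"))
    calls
  })

  report$outliers <- run_stage("classify_outliers", {
    out <- classify_outliers(report$per_gene, report$selection,
                             thresholds = config$thresholds)
    write_tsv(out, out_path("outliers.tsv"))
    out
  })

  geneset_genomic <- readLines(config$geneset_genomic)
  report$selection_enrichment <- run_stage("selection_enrichment", {
    enr <- set_vs_genome_enrichment(report$selection, geneset_genomic)
    write_tsv(enrichment_row(enr, config$seed), out_path("enrichment.tsv"))
    enr
  })

  report$kruskal <- run_stage("kruskal_wallis", {
    in_set <- report$per_gene$gene_id %in% geneset_genomic
    lapply(c(fst = "fst", dxy = "dxy"), function(metric) {
      v <- report$per_gene[[metric]]
      ok <- !is.na(v)
      if (sum(ok & in_set) == 0 || sum(ok & !in_set) == 0) return(NULL)
      kruskal_wallis(list(set = v[ok & in_set], rest = v[ok & !in_set]))
    })
  })

  report$concordance <- run_stage("concordance", {
    fish <- call_directions(read_tsv(config$fish_de_tsv),
                            alpha = config$alpha)
    human <- call_directions(read_tsv(config$human_de_tsv),
                             alpha = config$alpha)
    map <- read_tsv(config$ortholog_map_tsv)
    res <- concordance(fish, human, map)
    write_tsv(res$genes, out_path("concordance_genes.tsv"))
    og <- orthogroup_summary(fish, map)
    write_tsv(og$rates, out_path("orthogroup_rates.tsv"))
    list(concordance = res, orthogroups = og)
  })

  report$bootstrap <- run_stage("bootstrap_enrichment", {
    fish_de <- read_tsv(config$fish_de_tsv)
    sig <- setNames(!is.na(fish_de$padj) & fish_de$padj < config$alpha,
                    fish_de$gene_id)
    bootstrap_expression_enrichment(
      sig, readLines(config$geneset_expression),
      n_boot = config$n_boot,
      sample_size = min(config$sample_size, length(sig)),
      seed = config$seed)
  })

  run_stage("manifest", write_manifest(config, completed))
  class(report) <- "pipeline_report"
  report
}

enrichment_row <- function(enr, seed) {
  data.frame(a = enr$table[1, 1], b = enr$table[1, 2],
             c = enr$table[2, 1], d = enr$table[2, 2],
             chi_square = enr$chi_square$statistic, df = enr$chi_square$df,
             p_value = enr$chi_square$p_value,
             odds_ratio = enr$odds_ratio$or,
             ci_lower = enr$odds_ratio$ci_lower,
             ci_upper = enr$odds_ratio$ci_upper,
             seed = seed)
}

write_manifest <- function(config, completed, failed = NULL) {
  manifest <- list(
    package = "divscan",
    seed = config$seed,
    parameters = list(
      min_individuals = config$min_individuals, alpha = config$alpha,
      n_boot = config$n_boot, sample_size = config$sample_size,
      fst_top_fraction = config$thresholds$fst_top_fraction,
      dxy_top_fraction = config$thresholds$dxy_top_fraction,
      hapflk_alpha = config$thresholds$hapflk_alpha,
      pi_exclude_count = config$thresholds$pi_exclude_count),
    inputs = config[c("vcf", "genes_bed", "populations_tsv", "stats_tsv",
                      "fish_de_tsv", "human_de_tsv", "ortholog_map_tsv",
                      "geneset_genomic", "geneset_expression")],
    completed_stages = as.list(completed))
  if (!is.null(failed)) manifest$failed_stage <- failed
  yaml::write_yaml(manifest, file.path(config$out_dir, "MANIFEST.yaml"))
  invisible(manifest)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("divscan pipeline report\n")
  cat(sprintf("  %d genes with data; %d divergence outliers (%d F_ST, %d D_XY, %d selection)\n",
              nrow(x$outliers), sum(x$outliers$is_outlier),
              sum(x$outliers$fst_outlier), sum(x$outliers$dxy_outlier),
              sum(x$outliers$hapflk_significant)))
  enr <- x$selection_enrichment
  cat(sprintf("  selection enrichment: %.1f%% of set vs %.1f%% of genome; X2 = %.2f, OR = %.2f\n",
              100 * enr$set_rate, 100 * enr$genome_rate,
              enr$chi_square$statistic, enr$odds_ratio$or))
  conc <- x$concordance$concordance
  cat(sprintf("  concordance: %d / %d same direction (%.1f%%)\n",
              conc$n_same_direction, conc$n_jointly_de,
              conc$percent_same_direction))
  cat(sprintf("  bootstrap percentile of the expression set: %s\n",
              x$bootstrap$percentile_label))
  invisible(x)
}

#' Write a complete synthetic input bundle for the pipeline
#'
#' Materializes every file [run_pipeline()] consumes from one
#' [sim_config()]: VCF genotypes, gene BED, population map, selection
#' statistics, DE tables, ortholog map, gene-set lists and the truth
#' tables. The genomic gene set contains all planted divergence-outlier
#' genes topped up with random background genes to a quarter of the
#' genome (capped at `geneset_size`), so planted enrichment is visible to
#' the selection-enrichment stage.
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @return A [pipeline_config()] pointing at the written files, with the
#'   truth tables attached as `attr(, "truth")`.
#' @export
write_sim_inputs <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(name) file.path(dir, name)

  sim <- simulate_genotypes(config)
  write_sim_vcf(sim, p("genotypes.vcf"))
  write_bed(sim$genes, p("genes.bed"))
  samples <- data.frame(
    sample = c(colnames(sim$geno[[1]]), colnames(sim$geno[[2]])),
    population = rep(names(sim$geno), times = vapply(sim$geno, ncol, 1L)))
  write_tsv(samples, p("populations.tsv"))

  stats <- simulate_selection_stats(config, sim$truth, sim$genes)
  write_tsv(stats, p("selection_stats.tsv"))

  de <- simulate_de_tables(config)
  write_tsv(de$fish, p("fish_de.tsv"))
  write_tsv(de$human, p("human_de.tsv"))
  write_tsv(de$map, p("ortholog_map.tsv"))
  writeLines(de$gene_set$fish, p("geneset_expression.txt"))

  set.seed(config$seed + 3L)
  size <- min(config$geneset_size, max(1L, config$n_genes %/% 4L))
  planted <- sim$truth$gene_id[sim$truth$planted]
  fill <- setdiff(sim$truth$gene_id, planted)
  genomic_set <- c(planted, sample(fill, max(0L, size - length(planted))))
  writeLines(genomic_set, p("geneset_genomic.txt"))

  write_tsv(sim$truth, p("truth_genes.tsv"))
  write_tsv(de$truth$fish, p("truth_fish_de.tsv"))
  write_tsv(de$truth$human, p("truth_human_de.tsv"))

  cfg <- pipeline_config(
    vcf = p("genotypes.vcf"), genes_bed = p("genes.bed"),
    populations_tsv = p("populations.tsv"), stats_tsv = p("selection_stats.tsv"),
    fish_de_tsv = p("fish_de.tsv"), human_de_tsv = p("human_de.tsv"),
    ortholog_map_tsv = p("ortholog_map.tsv"),
    geneset_genomic = p("geneset_genomic.txt"),
    geneset_expression = p("geneset_expression.txt"),
    out_dir = file.path(dir, "results"), seed = config$seed)
  attr(cfg, "truth") <- list(genes = sim$truth, de = de$truth)
  cfg
}
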