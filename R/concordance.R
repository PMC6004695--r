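#' Benjamini-Hochberg adjusted p-values
#'
#' The step-up false-discovery-rate procedure: sort the m raw p-values,
#' multiply the i-th smallest by m/i, enforce monotonicity from the
#' largest down (cumulative minimum) and cap at 1. Adjusted values are
#' never below the raw values.
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\] (`NA`s are
#'   propagated and ignored in m).
#' @return adjusted p-values, same length and order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  out <- rep(NA_real_, length(p_values))
  if (m > 0) {
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
    out[ok] <- adj
  }
  out
}

#' Call per-gene expression direction
#'
#' A gene is "up" when its adjusted p-value is below `alpha` and its log2
#' fold-change is positive, "down" when below `alpha` with a negative
#' fold-change, and "ns" otherwise. Significant genes with a fold-change
#' of exactly zero have no direction; they are set to `NA` with a
#' warning.
#'
#' @param table DE table with `gene_id`, `log2fc`, `padj`.
#' @param alpha significance level on the adjusted p-values.
#' @return data.frame: `gene_id`, `direction` (factor up/down/ns, `NA`
#'   for the degenerate zero-fold-change case).
#' @examples
#' call_directions(data.frame(gene_id = c("a", "b"),
#'                            log2fc = c(1.2, -0.8),
#'                            padj = c(0.001, 0.2)))
#' @export
call_directions <- function(table, alpha = 0.05) {
  stopifnot(all(c("gene_id", "log2fc", "padj") %in% names(table)))
  sig <- !is.na(table$padj) & table$padj < alpha
  dir <- rep("ns", nrow(table))
  dir[sig & table$log2fc > 0] <- "up"
  dir[sig & table$log2fc < 0] <- "down"
  zero <- sig & table$log2fc == 0
  if (any(zero)) {
    warning(sum(zero), " significant gene(s) with log2 fold-change 0 excluded")
    dir[zero] <- NA_character_
  }
  data.frame(gene_id = table$gene_id,
             direction = factor(dir, levels = c("up", "down", "ns")),
             stringsAsFactors = FALSE)
}

#' Summarize differential expression at the orthogroup level
#'
#' An orthogroup (all fish paralogs sharing the ancestor of one human
#' gene) is called significant when at least one member paralog is
#' significant -- the "any-paralog" rule. Returns the dual tabulation the
#' cross-species comparison reports: rates over orthogroups and over all
#' paralogs.
#'
#' @param directions per-paralog calls from [call_directions()] on the
#'   fish DE table.
#' @param map ortholog map with `human_id`, `orthogroup`, `fish_id`.
#' @return list: `orthogroups` (per-orthogroup `significant` flag and
#'   member direction summary), `rates` (orthogroup-level and
#'   paralog-level significant fractions and counts), `unmapped`
#'   (paralogs absent from the map).
#' @export
orthogroup_summary <- function(directions, map) {
  stopifnot(all(c("human_id", "orthogroup", "fish_id") %in% names(map)))
  if (anyDuplicated(map$fish_id)) {
    stop("each fish paralog must map to exactly one orthogroup",
         call. = FALSE)
  }
  m <- match(directions$gene_id, map$fish_id)
  unmapped <- directions$gene_id[is.na(m)]
  d <- directions[!is.na(m), , drop = FALSE]
  og <- map$orthogroup[m[!is.na(m)]]
  sig <- d$direction %in% c("up", "down")

  og_sig <- tapply(sig, og, any)
  og_dir <- tapply(seq_along(og), og, function(i) {
    dirs <- unique(as.character(d$direction[i][sig[i]]))
    if (length(dirs) == 1L) dirs else if (length(dirs) > 1L) "inconsistent"
    else "ns"
  })
  orthogroups <- data.frame(orthogroup = names(og_sig),
                            significant = as.logical(og_sig),
                            direction = as.character(og_dir),
                            stringsAsFactors = FALSE)
  list(
    orthogroups = orthogroups,
    rates = data.frame(
      level = c("orthogroup", "paralog"),
      n_significant = c(sum(orthogroups$significant), sum(sig)),
      n_total = c(nrow(orthogroups), length(sig)),
      rate = c(mean(orthogroups$significant), mean(sig)),
      stringsAsFactors = FALSE
    ),
    unmapped = unmapped
  )
}

#' Cross-species direction concordance
#'
#' Scores, at the fish-paralog level, how often differential expression
#' shifts in the same direction in the two species: a paralog is jointly
#' DE when both it and its mapped human gene have a direction (up or
#' down), and concordant when the directions match. Human genes whose
#' direction conflicts across reports must be resolved (or excluded)
#' upstream; pass them in `excluded_human` so the count is carried into
#' the result.
#'
#' @param fish_directions per-paralog calls ([call_directions()] on the
#'   fish table).
#' @param human_directions per-human-gene calls (aggregated over reports).
#' @param map ortholog map (`human_id`, `orthogroup`, `fish_id`).
#' @param excluded_human human gene ids excluded for inconsistent
#'   directions across reports; any paralog of these is dropped.
#' @return An object of class `concordance_result`: `n_jointly_de`,
#'   `n_same_direction`, `percent_same_direction`, `n_excluded_inconsistent`,
#'   and the per-paralog record `genes`.
#' @examples
#' map <- data.frame(human_id = "h1", orthogroup = "og1", fish_id = "f1")
#' fish <- data.frame(gene_id = "f1", log2fc = 2, padj = 0.01)
#' human <- data.frame(gene_id = "h1", log2fc = 1, padj = 0.01)
#' concordance(call_directions(fish), call_directions(human), map)
#' @export
concordance <- function(fish_directions, human_directions, map,
                        excluded_human = character()) {
  if (nrow(map) == 0L) stop("empty ortholog map", call. = FALSE)
  map <- map[!map$human_id %in% excluded_human, , drop = FALSE]
  fish_dir <- as.character(fish_directions$direction[
    match(map$fish_id, fish_directions$gene_id)])
  human_dir <- as.character(human_directions$direction[
    match(map$human_id, human_directions$gene_id)])

  has_dir <- function(d) !is.na(d) & d %in% c("up", "down")
  joint <- has_dir(fish_dir) & has_dir(human_dir)
  same <- joint & fish_dir == human_dir

  genes <- data.frame(fish_id = map$fish_id, human_id = map$human_id,
                      fish_direction = fish_dir, human_direction = human_dir,
                      jointly_de = joint, same_direction = same,
                      stringsAsFactors = FALSE)
  structure(list(
    n_jointly_de = sum(joint),
    n_same_direction = sum(same),
    percent_same_direction = if (sum(joint) > 0)
      100 * sum(same) / sum(joint) else NA_real_,
    n_excluded_inconsistent = length(excluded_human),
    genes = genes
  ), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "Direction concordance: %d of %d jointly DE genes in the same direction (%.1f%%)\n",
    x$n_same_direction, x$n_jointly_de, x$percent_same_direction))
  if (x$n_excluded_inconsistent > 0) {
    cat(sprintf("  %d human gene(s) excluded for inconsistent directions across reports\n",
                x$n_excluded_inconsistent))
  }
  invisible(x)
}

#' Resolve human directions across multiple reports
#'
#' Aggregates per-report direction calls for the same human genes: a gene
#' keeps a direction when every report that assigns one agrees (reports
#' silent on a gene do not vote), and is flagged inconsistent -- and
#' excluded from concordance -- when reports disagree.
#'
#' @param direction_tables list of per-report direction data.frames (from
#'   [call_directions()]).
#' @return list: `directions` (merged calls) and `excluded` (gene ids
#'   with conflicting directions).
#' @export
aggregate_human_directions <- function(direction_tables) {
  stopifnot(length(direction_tables) >= 1L)
  all_ids <- unique(unlist(lapply(direction_tables, `[[`, "gene_id")))
  dir_mat <- vapply(direction_tables, function(t) {
    as.character(t$direction[match(all_ids, t$gene_id)])
  }, character(length(all_ids)))
  dir_mat <- matrix(dir_mat, nrow = length(all_ids))
  pick <- apply(dir_mat, 1L, function(d) {
    d <- d[!is.na(d) & d %in% c("up", "down")]
    u <- unique(d)
    if (length(u) == 0L) "ns" else if (length(u) == 1L) u else "conflict"
  })
  excluded <- all_ids[pick == "conflict"]
  directions <- data.frame(
    gene_id = all_ids[pick != "conflict"],
    direction = factor(pick[pick != "conflict"], levels = c("up", "down", "ns")),
    stringsAsFactors = FALSE)
  list(directions = directions, excluded = excluded)
}

#' Pairwise chi-square comparison of DE rates across models
#'
#' For every pair of models/datasets, tests the 2x2 table (DE, not-DE) x
#' (model A, model B) with the Yates-corrected chi-square and multiplies
#' the p-values by the number of pairwise tests (Bonferroni), capping at
#' 1.
#'
#' @param results data.frame with `model`, `n_de`, `n_total`.
#' @return data.frame of pairwise tests: both models, statistic, raw and
#'   Bonferroni-corrected p-values, and the correction factor.
#' @export
cross_model_comparison <- function(results) {
  stopifnot(all(c("model", "n_de", "n_total") %in% names(results)),
            nrow(results) >= 2L)
  if (any(results$n_total <= 0)) stop("zero total counts", call. = FALSE)
  pairs <- utils::combn(nrow(results), 2L)
  n_tests <- ncol(pairs)
  out <- do.call(rbind, lapply(seq_len(n_tests), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    tab <- matrix(c(results$n_de[i], results$n_total[i] - results$n_de[i],
                    results$n_de[j], results$n_total[j] - results$n_de[j]),
                  nrow = 2L, byrow = TRUE)
    ct <- yates_chi_square(tab)
    data.frame(model_a = results$model[i], model_b = results$model[j],
               statistic = ct$statistic, df = ct$df, p_raw = ct$p_value,
               p_bonferroni = min(1, ct$p_value * n_tests),
               n_tests = n_tests, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
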