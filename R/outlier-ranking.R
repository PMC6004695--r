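#' Dense ranks
#'
#' Ranks values so that ties share a rank and ranks are consecutive
#' integers starting at 1: the higher the rank, the higher the value
#' (e.g. 0.02, 0.03, 0.04, 0.04 ranks as 1, 2, 3, 3). `NA` values are
#' excluded from ranking and stay `NA`.
#'
#' @param values numeric vector.
#' @return integer vector of the same length.
#' @examples
#' dense_rank(c(0.02, 0.03, 0.04, 0.04))
#' @export
dense_rank <- function(values) {
  if (all(is.na(values))) stop("all values are missing", call. = FALSE)
  match(values, sort(unique(values[!is.na(values)])))
}

#' Outlier-calling thresholds
#'
#' The genome-wide cut-offs of the multi-metric divergence-outlier
#' classification: the top 5% of per-gene F_ST, the top 20% of D_XY
#' (a less sensitive measure, hence the laxer default; 0.05 is the
#' supported stricter alternative), a per-gene selection-scan significance
#' level of 0.05, and exclusion of the 500 lowest-diversity genes
#' (surface-population pi) as likely low-recombination regions.
#'
#' @param fst_top_fraction,dxy_top_fraction top fractions in (0, 1).
#' @param hapflk_alpha per-gene selection-call significance level.
#' @param pi_exclude_count how many lowest surface-pi genes to exclude
#'   from outlier calling.
#' @return An `outlier_thresholds` list.
#' @export
outlier_thresholds <- function(fst_top_fraction = 0.05,
                               dxy_top_fraction = 0.20,
                               hapflk_alpha = 0.05,
                               pi_exclude_count = 500L) {
  for (f in c(fst_top_fraction, dxy_top_fraction, hapflk_alpha)) {
    if (!is.numeric(f) || f <= 0 || f >= 1) {
      stop("threshold fractions must lie strictly inside (0, 1)",
           call. = FALSE)
    }
  }
  if (pi_exclude_count < 0) stop("pi_exclude_count must be >= 0", call. = FALSE)
  structure(list(fst_top_fraction = fst_top_fraction,
                 dxy_top_fraction = dxy_top_fraction,
                 hapflk_alpha = hapflk_alpha,
                 pi_exclude_count = as.integer(pi_exclude_count)),
            class = "outlier_thresholds")
}

#' Classify multi-metric divergence outliers
#'
#' Ranks every per-gene metric genome wide with [dense_rank()] (genes
#' missing a metric are excluded from that metric's ranking), applies the
#' top-fraction cut-offs, copies the per-gene selection-scan flag, and
#' excludes the lowest-diversity genes before calling outliers. A gene is
#' a divergence outlier when it is not pi-excluded and meets any of the
#' three criteria: F_ST dense rank strictly above
#' `(1 - fst_top_fraction) * R_max` (with `R_max` that metric's maximum
#' dense rank, so boundary ties share fate), the analogous D_XY cut-off,
#' or a significant selection call.
#'
#' The pi exclusion removes the `pi_exclude_count` genes with the
#' smallest surface-population pi (ties broken by gene id for
#' determinism) from outlier *calling*; by default the ranks of the other
#' genes are computed on the full table. Set `rerank_after_pi_exclusion`
#' to recompute all ranks after dropping the excluded genes.
#'
#' @param stats per-gene statistics (from [per_gene_stats()]); the first
#'   `pi_` column is taken as the surface-like population's diversity.
#' @param calls per-gene selection calls (from [gene_selection_calls()]);
#'   genes absent from `calls` have no selection data and simply cannot
#'   meet that criterion.
#' @param thresholds an [outlier_thresholds()].
#' @param rerank_after_pi_exclusion recompute ranks on the table with
#'   pi-excluded genes removed.
#' @return data.frame: `gene_id`, dense ranks (`rank_pi_*`, `rank_fst`,
#'   `rank_dxy`), flags (`fst_outlier`, `dxy_outlier`,
#'   `hapflk_significant`, `pi_excluded`), `n_metrics_met` and
#'   `is_outlier`. Genes with no retained sites at all are dropped
#'   ("genes with no data were removed").
#' @export
classify_outliers <- function(stats, calls,
                              thresholds = outlier_thresholds(),
                              rerank_after_pi_exclusion = FALSE) {
  stopifnot(inherits(thresholds, "outlier_thresholds"))
  pi_cols <- grep("^pi_", names(stats), value = TRUE)
  stopifnot(length(pi_cols) >= 1L, all(c("fst", "dxy") %in% names(stats)))
  pi_surface <- pi_cols[1]

  out <- stats[!(is.na(stats$fst) & is.na(stats$dxy) & is.na(stats[[pi_surface]])),
               , drop = FALSE]

  # lowest-pi exclusion: smallest surface-pi genes, ties by gene id
  ord <- order(out[[pi_surface]], out$gene_id, na.last = TRUE)
  n_excl <- min(thresholds$pi_exclude_count,
                sum(!is.na(out[[pi_surface]])))
  pi_excluded <- rep(FALSE, nrow(out))
  if (n_excl > 0) pi_excluded[ord[seq_len(n_excl)]] <- TRUE

  rank_universe <- if (rerank_after_pi_exclusion) !pi_excluded else
    rep(TRUE, nrow(out))
  rank_of <- function(values) {
    r <- rep(NA_integer_, length(values))
    idx <- rank_universe & !is.na(values)
    if (any(idx)) r[idx] <- dense_rank(values[idx])
    r
  }
  top_flag <- function(ranks, fraction) {
    r_max <- suppressWarnings(max(ranks, na.rm = TRUE))
    flag <- !is.na(ranks) & ranks > (1 - fraction) * r_max
    flag
  }

  res <- data.frame(gene_id = out$gene_id, stringsAsFactors = FALSE)
  for (pc in pi_cols) res[[paste0("rank_", pc)]] <- rank_of(out[[pc]])
  res$rank_fst <- rank_of(out$fst)
  res$rank_dxy <- rank_of(out$dxy)
  res$fst_outlier <- top_flag(res$rank_fst, thresholds$fst_top_fraction)
  res$dxy_outlier <- top_flag(res$rank_dxy, thresholds$dxy_top_fraction)

  m <- match(res$gene_id, calls$gene_id)
  res$hapflk_significant <- !is.na(m) & calls$min_p[m] < thresholds$hapflk_alpha
  res$hapflk_significant[is.na(res$hapflk_significant)] <- FALSE
  res$pi_excluded <- pi_excluded
  res$n_metrics_met <- res$fst_outlier + res$dxy_outlier +
    res$hapflk_significant
  res$is_outlier <- !res$pi_excluded & res$n_metrics_met > 0L
  rownames(res) <- NULL
  res
}
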