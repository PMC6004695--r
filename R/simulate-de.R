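#' Simulate cross-species differential-expression tables with known truth
#'
#' Builds the three linked inputs of the expression-concordance analysis:
#' a human case-control DE table, a fish (case population vs control
#' population) DE table for 1-2 paralogs per human gene, and the
#' ortholog/orthogroup map connecting them, plus a focal gene set with a
#' planted enrichment.
#'
#' Each human gene is differentially expressed with probability
#' `de_fraction` (`min(1, de_fraction * geneset_enrichment)` inside the
#' focal set), with a random up/down direction and log2 fold-change
#' `+/-de_effect` plus small Gaussian noise. Adjusted p-values are
#' simulated directly rather than refit from counts: below 0.05 for DE
#' genes, and `0.05 + 0.95 * Beta(2, 1)` (skewed towards 1, as adjusted
#' p-values are under the null) otherwise. Every paralog of a DE human
#' gene is DE in fish and matches the human direction with probability
#' `concordance_rate`; paralogs of non-DE human genes are not DE.
#'
#' @param config a [sim_config()].
#' @return An object of class `de_sim`: a list with DE tables `fish` and
#'   `human` (`gene_id`, `log2fc`, `padj`), the `map`
#'   (`human_id`, `orthogroup`, `fish_id`), `gene_set` (a list with the
#'   `human` member ids and their `fish` paralog ids), and `truth` (a list
#'   of per-human-gene and per-paralog data.frames carrying DE status,
#'   directions, concordance and set membership).
#' @examples
#' de <- simulate_de_tables(sim_config(seed = 2, n_genes = 50,
#'                                     geneset_size = 10))
#' head(de$fish)
#' mean(de$truth$human$de)
#' @export
simulate_de_tables <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)

  n <- config$n_genes
  human_id <- sprintf("HG%05d", seq_len(n))
  orthogroup <- sprintf("OG%05d", seq_len(n))
  n_paralogs <- 1L + rbinom(n, 1L, 0.4)
  in_set <- rep(FALSE, n)
  in_set[sample.int(n, config$geneset_size)] <- TRUE

  p_de <- ifelse(in_set, pmin(1, config$de_fraction * config$geneset_enrichment),
                 config$de_fraction)
  de <- runif(n) < p_de
  dir_h <- ifelse(runif(n) < 0.5, 1, -1)

  sim_table <- function(id, de, dir) {
    lfc <- ifelse(de, dir * (config$de_effect + abs(rnorm(length(id), 0, 0.2))),
                  rnorm(length(id), 0, 0.1))
    padj <- ifelse(de, runif(length(id), 0, 0.049),
                   0.05 + 0.95 * rbeta(length(id), 2, 1))
    data.frame(gene_id = id, log2fc = lfc, padj = padj,
               stringsAsFactors = FALSE)
  }
  human <- sim_table(human_id, de, dir_h)

  gi <- rep.int(seq_len(n), n_paralogs)
  suffix <- unlist(lapply(n_paralogs, function(k) letters[seq_len(k)]),
                   use.names = FALSE)
  fish_id <- paste0(tolower(sub("^HG", "fishg", human_id[gi])), suffix)
  map <- data.frame(human_id = human_id[gi], orthogroup = orthogroup[gi],
                    fish_id = fish_id, stringsAsFactors = FALSE)

  de_f <- de[gi]
  concordant <- runif(length(gi)) < config$concordance_rate
  dir_f <- ifelse(concordant, dir_h[gi], -dir_h[gi])
  fish <- sim_table(fish_id, de_f, dir_f)

  structure(list(
    fish = fish, human = human, map = map,
    gene_set = list(human = human_id[in_set],
                    fish = fish_id[in_set[gi]]),
    truth = list(
      human = data.frame(gene_id = human_id, de = de,
                         direction = ifelse(de, dir_h, 0L),
                         in_set = in_set, stringsAsFactors = FALSE),
      fish = data.frame(gene_id = fish_id, human_id = human_id[gi],
                        de = de_f,
                        direction = ifelse(de_f, dir_f, 0L),
                        concordant = de_f & concordant,
                        in_set = in_set[gi], stringsAsFactors = FALSE)
    ),
    config = config
  ), class = "de_sim")
}
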