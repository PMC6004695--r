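#' Gene and mask annotation
#'
#' Bundles the interval inputs of the site filters and per-gene
#' aggregation: gene intervals, repeat-mask intervals, and indel-affected
#' spans. All intervals follow the BED convention (0-based, half-open);
#' VCF site positions are 1-based, and a site at position P falls in
#' interval \[s, e) iff s <= P - 1 < e.
#'
#' @param genes data.frame with `chrom`, `start`, `end`, `gene_id`.
#' @param masks optional data.frame with `chrom`, `start`, `end`
#'   (repeat-masked spans); overlapping intervals are merged silently.
#' @param indels optional data.frame with `chrom`, `start`, `end`
#'   (bases affected by each indel).
#' @return An object of class `gene_annotation`.
#' @examples
#' ann <- gene_annotation(
#'   genes = data.frame(chrom = "chr1", start = 0, end = 100,
#'                      gene_id = "g1"),
#'   masks = data.frame(chrom = "chr1", start = 40, end = 50))
#' ann
#' @export
gene_annotation <- function(genes, masks = NULL, indels = NULL) {
  check_intervals <- function(df, what, need_id = FALSE) {
    if (is.null(df)) return(df[0, ])
    cols <- c("chrom", "start", "end", if (need_id) "gene_id")
    if (!all(cols %in% names(df))) {
      stop(sprintf("%s intervals need columns %s", what,
                   paste(cols, collapse = ", ")), call. = FALSE)
    }
    if (any(df$end < df$start)) {
      stop(sprintf("%s intervals must have non-negative length", what),
           call. = FALSE)
    }
    df
  }
  genes <- check_intervals(genes, "gene", need_id = TRUE)
  if (anyDuplicated(genes$gene_id)) {
    stop("gene ids must be unique", call. = FALSE)
  }
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  masks <- if (is.null(masks)) empty else check_intervals(masks, "mask")
  indels <- if (is.null(indels)) empty else check_intervals(indels, "indel")
  structure(list(genes = genes, masks = masks, indels = indels),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("Gene annotation: %d gene(s), %d mask interval(s), %d indel(s)\n",
              nrow(x$genes), nrow(x$masks), nrow(x$indels)))
  invisible(x)
}

# 0-based half-open intervals -> GRanges (1-based closed, as GRanges expects)
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = pmax(df$end, df$start + 1L))
  )
}

sites_to_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = pos, width = 1L))
}

#' Read and write BED interval files
#'
#' Plain 0-based half-open BED, tab-separated, no header. Columns beyond
#' the fourth are ignored on read; a fourth `name` column becomes
#' `gene_id` when present.
#'
#' @param path file path.
#' @return `read_bed()`: a data.frame with `chrom`, `start`, `end` and,
#'   when present, `gene_id`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "gene_id", "V5", "V6")[
                     seq_len(min(6L, ncol(read.table(path, sep = "\t", nrows = 1L))))],
                   fill = TRUE)
  df[, intersect(c("chrom", "start", "end", "gene_id"), names(df)), drop = FALSE]
}

#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `gene_id`.
#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "gene_id"), names(intervals))
  write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write simulated genotypes as a minimal VCF
#'
#' Emits VCF v4.2 with GT-only FORMAT, `./.` for missing genotypes, and
#' the simulation seed recorded in the header. Alleles are arbitrary
#' (`A`/`T`) since only genotype dosages matter downstream.
#'
#' @param sim a `genotype_sim` object.
#' @param path output path (plain text).
#' @return `path`, invisibly. The sample-to-population assignment is
#'   recoverable from the sample names (`<population>_<nn>`).
#' @export
write_sim_vcf <- function(sim, path) {
  geno <- cbind(sim$geno[[1]], sim$geno[[2]])
  gt <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], nrow = nrow(geno))
  gt[is.na(geno)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=divscan simulate_genotypes seed=%d", sim$config$seed),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(geno)), collapse = "\t")
  )
  body <- paste(sim$sites$chrom, sim$sites$pos, ".", "A", "T", ".", "PASS",
                ".", "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a two-population VCF into per-site allele counts
#'
#' Parses GT fields with \pkg{vcfR}, keeps biallelic SNPs only (single-base
#' REF and ALT; multiallelic records are dropped at parse time), and
#' collapses genotypes to per-population allele counts.
#'
#' @param path VCF file (plain or bgzipped).
#' @param populations named list of two character vectors of sample names,
#'   e.g. `list(surface = c(...), cave = c(...))`.
#' @return A `site_counts` data.frame (see [allele_counts()]).
#' @export
read_vcf_counts <- function(path, populations) {
  stopifnot(length(populations) == 2L, !is.null(names(populations)))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  snp <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"], fixed = TRUE)
  gt <- vcfR::extract.gt(vcf, element = "GT")[snp, , drop = FALSE]
  dosage <- function(g) {
    # count "1" alleles; any missing allele -> NA genotype
    d <- (substr(g, 1L, 1L) == "1") + (substr(g, 3L, 3L) == "1")
    d[substr(g, 1L, 1L) == "." | substr(g, 3L, 3L) == "."] <- NA_integer_
    d
  }
  geno <- lapply(populations, function(samples) {
    missing <- setdiff(samples, colnames(gt))
    if (length(missing) > 0) {
      stop("samples absent from VCF: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    g <- gt[, samples, drop = FALSE]
    matrix(dosage(g), nrow = nrow(g), dimnames = dimnames(g))
  })
  sites <- data.frame(chrom = fix[snp, "CHROM"],
                      pos = as.integer(fix[snp, "POS"]),
                      stringsAsFactors = FALSE)
  allele_counts(geno, sites = sites)
}

#' Read/write tab-separated tables with a header line
#'
#' Thin wrappers fixing the dialect every stage of the pipeline uses:
#' tab-separated, header line, `NA` for missing.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @rdname tsv
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tsv
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
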