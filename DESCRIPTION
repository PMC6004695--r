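Package: divscan
Title: Per-Gene Divergence Scans, Selection-Signal Enrichment and
    Cross-Species Expression Concordance for Two-Population Genomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for linking population-genomic divergence between two
    populations to candidate gene sets. Computes per-gene nucleotide
    diversity (pi), Weir-Cockerham F_ST and absolute divergence D_XY from
    biallelic genotype data under repeat-mask, indel-proximity and
    missing-data site filters; converts externally computed per-SNP
    selection-scan statistics into per-gene selection calls via a
    genome-wide normal fit; classifies multi-metric divergence outliers
    with dense genome-wide ranks and a low-diversity exclusion; tests
    gene-set enrichment with the Yates-corrected chi-square, odds ratios,
    Kruskal-Wallis comparisons and a bootstrap resampling null; and scores
    the direction concordance of differential expression between species
    through an ortholog/paralog map. Includes a Balding-Nichols
    two-population simulator with planted divergence outliers, selection
    signals, differential expression and gene-set enrichment so that every
    stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
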