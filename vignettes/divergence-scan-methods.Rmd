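---
title: "Methods: per-gene divergence scans, enrichment tests and cross-species concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-gene divergence scans, enrichment tests and cross-species concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divscan)
```

## The analysis chain

`divscan` implements the inference chain that links population-genomic
divergence between two populations (a "surface"-like control population
and a "cave"-like derived population, in the cavefish setting the package
was designed around) and cross-species expression shifts to a candidate
gene set. The chain has five stages, each usable on its own:

1. **Site filtering** — from biallelic genotypes, drop repeat-masked
   sites, indel-affected bases plus a 10 bp flank on each side, and sites
   genotyped in fewer than six individuals in either population.
2. **Per-gene divergence statistics** — nucleotide diversity ($\pi$) per
   population, Weir–Cockerham $F_{ST}$, and absolute divergence $D_{XY}$,
   aggregated per gene.
3. **Selection calls** — externally computed per-SNP selection-scan
   statistics (a haplotype-based scan such as hapFLK in the motivating
   study) are converted to p-values by a genome-wide normal fit, and a
   gene is called selected when any SNP inside it has $p < 0.05$.
4. **Outlier classification** — genome-wide dense ranks; a gene is a
   divergence outlier when it is in the top 5% for $F_{ST}$, the top 20%
   for $D_{XY}$, or carries a significant selection call, unless it is
   among the 500 lowest-diversity genes.
5. **Enrichment and concordance** — 2×2 Yates chi-square and odds ratio
   of a focal gene set against the genome, Kruskal–Wallis comparisons of
   metric distributions, a bootstrap resampling null for expression
   significance rates, and direction concordance of differential
   expression (DE) across species through an ortholog/paralog map.

## Estimators and their numerical conventions

**Per-site $\pi$** is the unbiased expected heterozygosity
$2 p (1-p)\, n/(n-1)$, with $p$ the sample alternate-allele frequency and
$n$ the non-missing allele count; sites with $n < 2$ are skipped for that
population. **Per-site $D_{XY}$** is $p_1(1-p_2) + p_2(1-p_1)$, the
probability that one allele drawn from each population differs; it is
exactly symmetric in the populations. Both aggregate per gene as the mean
over retained sites. The mean (rather than the sum) keeps genes of
different lengths comparable, which matters because the outlier cut-offs
are genome-wide rank fractions.

**$F_{ST}$** uses the Weir–Cockerham variance-component estimator in its
allele-count (random-union-of-gametes) form, the natural choice when the
data container carries per-population allele counts rather than
individual heterozygosity. Per gene, the default is the ratio-of-sums
("weighted") form, $\sum_l a_l / \sum_l (a_l + b_l)$ over retained sites
$l$: the mean-of-ratios alternative (`method = "mean"`) is exposed but
not default, because single low-diversity sites make per-site ratios
unstable. Negative estimates are reported as-is — clamping would break
the monotonicity of the genome-wide ranking. Sites monomorphic in both
populations contribute zero to the $\pi$ and $D_{XY}$ means and nothing
to the $F_{ST}$ denominator; genes with no retained (or no polymorphic)
sites carry `NA`, never a fabricated zero.

**Coordinates.** BED intervals are 0-based half-open; VCF positions are
1-based. A site at 1-based position $P$ belongs to gene $[s, e)$ iff
$s \le P-1 < e$. SNPs inside overlapping genes count for every
overlapping gene. Multiallelic records are dropped at VCF parse time;
the pipeline consumes hard-filtered biallelic SNPs.

**Dense ranks.** Tied values share a rank and ranks are consecutive from
1 (0.02, 0.03, 0.04, 0.04 → 1, 2, 3, 3). A gene is a top-$x$ outlier for
a metric when its dense rank exceeds $(1 - x) R_{\max}$, with $R_{\max}$
the metric's maximum dense rank. Under this rule boundary ties share
fate: either every gene at the boundary value is an outlier or none is,
which avoids arbitrary tie-splitting. A consequence is that the flagged
fraction is at least (not exactly) the nominal fraction when ties
straddle the cut.

**Low-diversity exclusion.** The `pi_exclude_count` (default 500) genes
with the smallest surface-population $\pi$ are excluded from outlier
*calling*, since apparent $F_{ST}$ outliers in low-diversity regions are
often artifacts of low recombination. Ties at the exclusion boundary are
broken by gene id so the excluded set is deterministic. By default the
ranks of the remaining genes are still computed on the full table
(missing-data genes removed, pi-excluded genes included);
`rerank_after_pi_exclusion = TRUE` recomputes ranks after dropping the
excluded genes. Genes missing one metric can still be outliers through
another — the classification is a union ("any of the criteria"), not an
intersection.

**Selection p-values.** "Fitting a normal genome wide" is implemented as
standardization by the genome-wide mean and standard deviation followed
by the standard normal upper tail — one-sided, because larger scan
statistics indicate stronger evidence of selection; a two-sided variant
sits behind `two_sided = TRUE`. A constant statistic table is a
degenerate-input error, not a silent NaN. The scan's internal model
(haplotype clustering, kinship) is deliberately out of scope: the module
consumes its raw output.

## Enrichment statistics

The 2×2 test is the chi-square with Yates continuity correction,
$\sum (|O - E| - 0.5)^2 / E$ with the correction clamped at zero when
$|O - E| < 0.5$ — the statistic printed by the reports this package is
designed to reproduce (an exact Fisher p-value is available via
`exact = TRUE`). The genome row of the table includes the focal set by
default, matching the published construction; `disjoint = TRUE` compares
set against non-set. The odds ratio is the sample $ad/bc$ with a Woolf
log-scale interval and the Haldane–Anscombe +0.5 correction when a cell
is zero. Note that alternative OR estimators (conditional maximum
likelihood, as in `fisher.test`) give slightly different values on the
same table; the documented sample OR is what this package reports.
`yates_chi_square`, `kruskal_wallis` and `bh_adjust` are implemented
from their closed formulas, and the test suite cross-checks each against
the corresponding `stats::` routine to 1e-8 on randomized inputs — a
deliberate dual-route design, so the package's numbers are verified
rather than merely delegated.

The **bootstrap null** draws `n_boot = 9999` samples of
`sample_size = 500` genes without replacement from the expression
universe (with-replacement sampling sits behind a flag) and places the
focal set's percent-significant on that distribution. The percentile uses
strict inequality — replicates tied with the observed value count as
not-below, the conservative direction — and is displayed as "> 99.9"
when the observed value exceeds every replicate. Results are
bit-for-bit reproducible given the seed, which is recorded in the
result object and every report.

## Cross-species concordance

DE significance is $\alpha = 0.05$ on Benjamini–Hochberg adjusted
p-values; a gene's direction is the sign of its log2 fold-change.
Concordance is counted at the fish-paralog level: each paralog of a
human gene is scored independently against the human direction, because
paralogs are under separate regulatory control and the tabulations being
mirrored count paralogs separately. An orthogroup is significant when
*any* member paralog is — the only rule consistent with the orthogroup
rates exceeding paralog rates in the tabulations this mirrors — and an
orthogroup-level direction is assigned only when all significant
paralogs agree. On the human side, genes whose direction conflicts
across reports are excluded (and counted); reports silent on a gene do
not vote. Both rules are recorded in the output objects.

Pairwise comparisons of DE rates across models use the Yates 2×2
chi-square with Bonferroni correction (p multiplied by the number of
pairwise tests, capped at 1).

## The synthetic-data generator

The generator exists so every stage can be tested against known ground
truth without any external download. Its defaults describe the emulated
study design: 10 + 9 diploids (the resequencing core sets of the two
populations), genome-wide background differentiation `background_F =
0.2` (the observed genome-wide mean $F_{ST}$ scale between the cave and
surface populations), a 5% fraction of planted outlier genes at
`planted_F = 0.6`, roughly half of genes differentially expressed
(`de_fraction = 0.5`, the rate random gene samples show in the emulated
expression data), a planted cross-species concordance rate of 0.6, and a
500-gene focal set with a 1.3× DE-probability boost.

**Genotypes** follow the Balding–Nichols model: per gene one ancestral
frequency $p_0 \sim U(0.05, 0.95)$ (bounded away from 0/1 so sites
monomorphic in both populations do not dominate), and per site each
population's frequency is an independent
$\mathrm{Beta}(p_0(1-F)/F,\ (1-p_0)(1-F)/F)$ draw — mean $p_0$, variance
$F p_0 (1-p_0)$ — with $F$ the gene's divergence parameter. Under this
model the Weir–Cockerham estimand equals $F$ exactly
($\theta = F p_0 q_0 / (F p_0 q_0 + (1-F) p_0 q_0)$), which is what
makes the estimator-recovery tests sharp. Per-site draws (rather than
one frequency per gene) are what make a 50-site gene an informative
replicate; with a single draw per gene the per-gene estimate would have
the variance of a single site. Genotypes are binomial; missingness is
independent per genotype. $F$ at exactly 0 or 1 is rejected as
degenerate — the no-divergence and fixation limits are covered by
near-limit configurations (0.001, 0.99) instead.

**Selection statistics** are standard normal genome-wide with a positive
location shift (default +5 SD at 3 of 5 SNPs) inside planted genes.
**Adjusted p-values are simulated directly** — below 0.05 for DE genes,
$0.05 + 0.95\,\mathrm{Beta}(2,1)$ otherwise (skewed towards 1, as
adjusted p-values are under the null) — rather than simulating counts
and refitting a DE model, since DE model fitting is out of scope. Each
human gene maps to 1–2 fish paralogs (40% get a second paralog, giving
~1.4 paralogs per gene as in the ortholog tables being mirrored), and a
DE paralog matches the human direction with probability
`concordance_rate`.

Each generator consumes one PRNG stream derived from the single
configuration seed (small fixed offsets keep the genotype, selection and
DE draws independent), and the seed is recorded in the VCF header, the
pipeline manifest and every result object; identical configurations give
byte-identical outputs.

What the generator does **not** emulate: linkage and recombination
(sites are independent given the gene's $F$; a coalescent simulator
would be needed for haplotype structure, which is why the selection-scan
model itself stays external), demographic history, gene-length and GC
heterogeneity, and correlated missingness. Passing tests therefore show
that the estimator chain is correct and calibrated under the stated
sampling model, not that the biological conclusions of any particular
study are robust.

## Problem sizes used in the checks

The test suite and the acceptance script run at desk scale, chosen so
each property is measured with adequate precision: estimator recovery on
100 genes × 50 sites with 25 diploids per population (5000 sites total,
where the mean per-gene $F_{ST}$ estimates $F$ to within ±0.02);
outlier sensitivity on 500 genes with 4% planted at $F = 0.6$ against a
0.05 background; selection-call calibration on 2000 genes at 1, 5 and
10 SNPs per gene against the analytic rate $1 - 0.95^k$; bootstrap null
calibration over 200 runs at 999 replicates (uniformity of the
percentile, Kolmogorov–Smirnov); and concordance recovery at ~3000
jointly DE paralogs, where a planted rate of 0.6 is recovered within 3
percentage points. The full-scale bootstrap (9999 × 500) runs in the
acceptance script.

## Known limitations

- Exactly two populations; the multi-population generalizations of
  $F_{ST}$ and the scan post-processing are out of scope.
- Gene-based aggregation only — no sliding windows, no smoothing across
  neighboring genes.
- The low-diversity exclusion is a fixed count (500), not a diversity
  threshold; with genomes much smaller or larger than ~20k genes the
  count should be rescaled by the user.
- The 2×2 table construction includes the focal set in the genome row by
  default; with very large sets relative to the genome the disjoint
  construction is the better-calibrated choice.
- `NA` handling is deliberate throughout ("genes with no data were
  removed"): genes absent from a stage's input are absent from its
  output rather than imputed.
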