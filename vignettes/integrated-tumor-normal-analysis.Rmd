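---
title: "Methods: integrated paired tumor/normal analysis"
author: "PairedTumorKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated paired tumor/normal analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PairedTumorKit)
```

# Scope

PairedTumorKit implements the analysis core of an integrated paired
tumor/normal study of a genomically quiet pediatric tumor: contrastive
somatic SNV selection from allele depths, VAF-based LOH and copy-number
summarization, negative-binomial differential expression on RPKM-quantified
counts, and gene-set over-representation with cancer-gene candidate
ranking. Alignment, genotyping-based candidate generation, segmentation
and purity estimation are upstream of this package: its inputs are
per-site allele depths, exon/probe log2 depth ratios and raw count
matrices. A seeded synthetic-cohort generator with full ground truth makes
every stage testable end to end.

# Somatic selection from paired allele depths

At a site with tumor depths $(r_T, a_T)$ and normal depths $(r_N, a_N)$
(high-quality reads supporting the reference and the variant allele), each
sample's variant allele fraction is $\mathrm{VAF} = a/(r+a)$, undefined at
zero depth. The caller asks whether the tumor VAF exceeds the normal VAF
by a **read-label permutation test**: under the null hypothesis the
tumor/normal labels carry no information, so the $N = d_T + d_N$ pooled
reads (of which $K = a_T + a_N$ support the variant) are reassigned to the
two samples with each sample's depth held fixed. The number of variant
reads landing in the tumor slot is then hypergeometric, and the test
statistic — the VAF difference, chosen because it is well defined at
VAF 0 — is monotone in that count, so the one-sided p-value is the upper
hypergeometric tail $P(X \ge a_T)$. For total depth up to `exact_cap`
(default 1000, which covers a 150× exome design with margin) the tail is
computed exactly; above the cap a Monte Carlo estimate with add-one
smoothing, $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_\text{perm})$,
avoids zero p-values, and ties count as exceedances (conservative). Each
site's Monte Carlo stream is keyed on its read counts plus the run seed,
so results are deterministic and independent of input order.

Selection is joint, on the volcano axes: significance
($-\log_{10} p$) and effect
$\mathrm{VAF}_\mathrm{frac} = \mathrm{VAF}_T/(\mathrm{VAF}_T+\mathrm{VAF}_N)$,
which is near 1 for tumor-specific variants and near 0.5 for shared
germline ones. A site is `SOMATIC` only if depth in both samples reaches
`min_depth` (default 8), $p <$ `p_max` (default 0.05),
$\mathrm{VAF}_\mathrm{frac} \ge$ `frac_min` (default 0.9), and the normal
VAF is below 0.25 (`GERMLINE_LIKE` guard). The source study describes the
joint selection but prints no numeric cut-offs, so these defaults are this
package's own choices; they are explicit arguments and are echoed in the
pipeline manifest. Downstream filtering keeps non-synonymous-class calls
(`nonsynonymous`, `stop_gain`, `splice`) with population allele frequency
below 1%.

# LOH, gene-level copy number, windowed Z

LOH is defined directly on VAFs: a site heterozygous in the normal
(normal VAF in `[0.4, 0.6]`) whose tumor VAF has drifted to within
`hom_margin = 0.1` of 0 or 1. With tumor purity $p$, a heterozygously
deleted site is observed at VAF $1/(2-p)$ or $(1-p)/(2-p)$ — at $p = 0.9$
that is 0.909, right at the margin — so the per-site margin is
deliberately not widened; instead the regional aggregation calls a gene
`LOH` when at least 30% of its informative sites are per-site LOH, which
is robust to binomial straddling of the margin while keeping regions
without LOH far below the threshold.

Exon-level depth log2 ratios are summarized per gene by the **median**
(the aggregation function is unspecified in the source; the median is
robust to single-exon artifacts), with categories
`HOM_DEL` $\le -2$, `HET_DEL` $\le -0.5$, `GAIN` $\ge 0.5$ — again
package defaults, all configurable. Array probe tracks are scanned with
non-overlapping 1-Mb tiling windows scored by
$z = \bar{x}_w / (\hat\sigma/\sqrt{n_w})$, flagged at $|z| \ge 4$; the
global spread $\hat\sigma = 1.4826\,\mathrm{MAD}$ over all probes is
robust to the aberrant windows themselves. Windows with fewer than 10
probes are never flagged. With a degenerate zero MAD (noiseless input)
$z$ is defined as 0 for zero-mean windows and infinite otherwise, so
noiseless recovery is exact. Whether the original scan tiled or slid its
windows is not stated; tiling anchored at the chromosome start was chosen
for determinism.

The mechanism classifier combines the three signals in a fixed priority:
homozygous deletion alone is biallelic; a heterozygous deletion plus a
damaging somatic call is biallelic; copy-neutral (or gained) LOH plus a
damaging call is biallelic; a heterozygous deletion alone and everything
else are not.

# Expression: RPKM and the negative binomial test

RPKM is the standard closed form
$10^9 \, k_{gs} / (\ell_g \, M_s)$ with $\ell_g$ the transcript length
and $M_s$ the sample's mapped total (column sums by default, or supplied
externally). The two-group test is owned by the package rather than
delegated: median-of-ratios size factors; per-gene method-of-moments
dispersion pooled within groups, shrunk toward a fitted $a_0 + a_1/\mu$
dispersion–mean trend with weight $\mathrm{df}/(\mathrm{df} + 10)$ on the
per-gene estimate (the prior strength of 10 pseudo-degrees balances
per-gene noise at $n = 9$ against trend misfit); and a two-sided exact
conditional test that, given a gene's total count, accumulates the
probability of all tumor/control splits at most as probable as the
observed one under the fitted NB model. Genes whose conditional sum
exceeds 50,000 counts switch to a Wald test on the difference of log
normalized group means (the normal approximation is excellent there).
All-zero genes report $p = 1$, fold change 0, and a flag.

DEG selection mirrors the asymmetric thresholds of the source study's
heatmap legend: `UP` requires $\log_2\mathrm{FC} > 1$ and $p < 0.05$;
`DOWN` requires $\log_2\mathrm{FC} < -1$ and the stricter $p < 0.001$.
The expression floor ("RPKM > 0.5") is interpreted as *mean RPKM of the
higher-expressed group* > 0.5 — the study does not say whether the floor
is per sample, per group or overall, and the higher-group mean is the
least destructive reading. Raw p-values are thresholded (as in the
source); BH q-values are reported alongside for transparency. Fold
changes use a 0.5 pseudocount on normalized group means, and per-sample
relative expression uses a 0.25 pseudo-RPKM guard.

# Enrichment, ranking, subgroup scoring

Over-representation is the hypergeometric upper tail
$P(X \ge k)$ of the query/set overlap in the universe of all genes tested
for differential expression (the universe choice materially changes
p-values; it is an explicit argument). The ranked-list KS flavor of
gene-set analysis is deliberately out of scope: the method consumes DEG
*lists*. BH correction is applied across the collection and records are
ordered by p with the set name as a deterministic tie-break. The
gene-by-set overlap matrix of the enriched sets is intersected with a
cancer-gene list and ranked by DEG p (then $|\log_2\mathrm{FC}|$, then
name); rank 1 is the top candidate — "most significant" is not formally
defined in the source, and smallest DEG p is the reading adopted.
Subgroup scoring computes, per sample, the mean log2 ratio of each
subgroup signature to a reference gene's expression and labels by
arg-max, with ties left `UNCLASSIFIED`.

# The synthetic cohort and what it does (not) show

The generator fixes the study conditions rather than exposing dials to
tune against: ~150× mean depth (Poisson per site and sample), tumor
purity 0.9, somatic variants planted at cell-level VAF 0.4 (observed at
purity × VAF), germline heterozygous sites at VAF 0.5 in both samples,
sequencing error $10^{-3}$ per base, one planted LOH region in which
germline sites drift to the purity-attenuated homozygous VAFs, a 4-tumor
vs 5-control count matrix with NB dispersion 0.1 and log-normal
library-size factors (sd 0.2), planted up/down DE fractions 0.06/0.035
(ratio ≈ 1.7, inside the 1.5–3 range such deregulated cohorts show) at
±2 log2 units on adequately expressed genes (baseline mean ≥ 50, so the
strict down-threshold is attainable at this design size), a driver gene
knocked down 2⁴-fold in tumors (its truth requirement is ≤ −2 log2), a
designated top cancer gene carrying the strongest planted effect
(+4 log2) and placed in the most enriched set and on the cancer list,
and three subgroup signatures elevated 4-fold in matching tumors relative
to a uniformly expressed reference gene. Purity is not calibrated to any
particular specimen — the source study defers per-sample purity to
supplementary material — and is configurable.

The generator emulates the *statistical* structure the analysis assumes:
binomial read sampling, NB counts, Gaussian track noise. It does not
simulate reads, indels, multi-allelic sites, fusions, GC or mappability
artifacts, batch effects beyond library size, or correlated genes.
Passing truth-recovery tests therefore demonstrates that the
implementation is correct *under its own model assumptions*, not that the
thresholds transfer to any particular real cohort.

Problem sizes used by the validation suite were chosen to make the
statistical assertions sharp at desk scale: 496 exhaustively enumerated
shallow-depth configurations for the permutation oracle, 20,000 null
sites for caller calibration, 5,500 sites (500 somatic) for truth
recovery, 2,000 genes for NB size and power, and the 5,000-gene default
cohort end to end.

# Numerical and reproducibility choices

Seeds: every generator derives a stage sub-seed from the master seed, so
single stages can be regenerated independently and identically; Monte
Carlo permutation streams are additionally keyed on site read counts,
making calls order-equivariant. Monte Carlo p-values are validated
against exact enumeration with exact central 99.73% binomial prediction
intervals rather than Gaussian ±3 SE bands: the Gaussian band is wrong in
the skewed small-$np$ regime, and across ~500 independent Monte Carlo
runs one to two boundary exceedances are expected by construction, so the
family-level check allows a small exceedance count instead of demanding
all runs inside (and the upper-half quantile is computed on the
complement, working around `qbinom()` instability for success
probabilities near 1). TSV output uses fixed 6-significant-digit
formatting and LF line endings so reruns are byte-identical; the pipeline
writes every threshold into `manifest.json` and the md5 of every output
into `report.json`.

# Limitations

The permutation test models read sampling only; it does not account for
mapping bias or strand artifacts, which real callers filter upstream.
The NB exact conditional test assumes the shrunk dispersion is correct;
strongly outlying dispersions at tiny sample sizes are only partially
protected by the prior. The LOH caller is per-site with a simple regional
vote, not a segmentation. The windowed Z scan has no within-window
correlation model. The enrichment stage assumes set membership is
error-free and the universe is exactly the tested genes.
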