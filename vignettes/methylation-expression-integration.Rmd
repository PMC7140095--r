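---
title: "Methylation–expression integration for small tumor/normal array studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation–expression integration for small tumor/normal array studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`methx` analyzes paired DNA-methylation (EPIC-style β values) and RNA
expression (gene-level counts) data from small tumor-versus-normal cohorts.
This vignette is the package's account of its statistical choices: what each
stage assumes, which knobs matter, what the synthetic generator does and does
not emulate, and where a genuinely open design question was settled one way.

## The differential-methylation model

A β value is the fraction of methylated signal at a CpG probe. Rather than
modelling β directly — β values are heteroskedastic, bounded and bimodal — the
caller discretizes each sample into three biologically interpretable states:

* low methylation: β ≤ 0.3,
* moderate methylation: 0.3 < β < 0.7,
* high methylation: β ≥ 0.7.

Both boundaries are closed toward the outer states, exactly as the thresholds
are written. Per probe, the group × state table (2 × 3) is tested with a
two-sided exact test under the multivariate hypergeometric null: with row and
column margins fixed, the p-value is the total probability of all tables whose
probability does not exceed that of the observed table. This is the natural
r×c generalization of Fisher's exact test and is the only exact choice at
these group sizes (10 vs 4 samples leaves no room for asymptotics; the
smallest attainable p is 1/C(14,4) ≈ 0.001).

The enumeration runs over the two free cells of the first row in log-gamma
arithmetic. Floating-point ties are counted as extreme within a relative
tolerance of 1e-12, so tables that are mathematically equiprobable with the
observed one are always included. The test suite checks the implementation
against a brute-force enumeration oracle written with a different probability
factorization (products of binomial coefficients) and against
`stats::fisher.test`.

Significance combines evidence and effect: a probe is called differentially
methylated when the Benjamini–Hochberg adjusted p-value is below `alpha`
(default 0.05) **and** |Δβ| ≥ `min_delta_beta` (default 0.3), where Δβ is the
tumor median β minus the normal median β. Medians, not means: with four
normals a single outlying sample would otherwise dominate the effect estimate.
The Δβ rule is interpreted as a threshold on the difference of group medians;
the alternative (median of per-pair differences) presupposes paired samples,
which this design does not have. Hyper- and hypomethylated calls are the
significant probes with positive and negative Δβ, so the two directions
always partition the significant set.

Three deliberate edge policies:

* Probes with a missing β in any retained sample are dropped before testing,
  with a logged count. The adjustment denominator is the tested probes.
* Zero-variance probes are still tested. Their table is degenerate and the
  test returns p = 1, which keeps the BH denominator stable across
  configuration changes instead of silently shrinking it.
* BH is applied once across all tested probes, not stratified by context.

Probe filtering precedes everything: cross-reactive probes, probes overlapping
polymorphisms with minor allele frequency above 5%, and sex-chromosome probes
are removed, each with a logged tally. With mixed-sex cohorts, chrX/chrY
probes would otherwise test sex, not tumor state.

## Differential expression

Genes enter the analysis when they are *expressed*: CPM > 1 in strictly more
than 80% of the samples of at least one group. The strictness matters at these
sizes — 8 of 10 tumors is exactly 80% and does not qualify.

The test is a per-gene negative-binomial GLM with a group covariate and a log
library-size offset. Two implementation choices deserve explanation:

* **Library sizes are median-of-ratios size factors**, not raw column totals.
  When differential expression is asymmetric (more mass gained than lost, or
  vice versa), raw totals are composition-biased and push every null gene's
  coefficient away from zero; the median of per-gene ratios to a reference
  (geometric-mean) sample is robust to a minority of changed genes. This is
  the standard meaning of "library size" in count-based differential
  expression.
* **The Wald statistic is referred to a t distribution with residual degrees
  of freedom** (n − 2), not a normal. At n = 14 the normal reference is
  anti-conservative; the t reference is the usual small-sample correction and
  is what lets the test hold its size in the package's permutation
  calibration tests.

The gene-wise dispersion is a method-of-moments estimate on size-factor
normalized counts, computed within each group and averaged, floored at 1e-8.
No shrinkage across genes is performed: the contract of this stage is
controlled type-I error and BH-significant calls, not equivalence with any
specific published differential-expression tool, and the package makes no such
claim. Genes whose GLM does not converge are reported with p = 1 and flagged.
log2 fold change is the group coefficient divided by ln 2.

## Signature scores

The thyroid differentiation score of a sample is the mean over signature
genes of (log2 expression − mean log2 expression in normals). It is linear in
log-expression, zero on average over normals by construction, and negative
when thyroid-function genes are collectively downregulated. The exact upstream
definition of this score is not restated in the sources the package follows,
so this transparent normal-centered form is used and documented as an
interpretation; the signature list is user-supplied.

The BRAF–RAS score is Pearson correlation with the RAS-like centroid minus
Pearson correlation with the BRAF-like centroid over the centroid genes
present in the data; negative scores classify as BRAF-like. Correlation makes
the score invariant to affine rescaling of a sample's expression vector.
Centroid provenance is the user's responsibility; the package ships only toy
centroids in its test suite.

Both scores use log2(CPM + 1); the pseudocount of 1 avoids −∞ at zero counts
and is applied uniformly.

## Integration

Quadrant membership requires *both* calls to be significant: a probe in a
promoter (manifest labels TSS1500/TSS200/5′UTR/1stExon) or gene body
(Body/ExonBnd) must itself be differentially methylated, and its mapped gene
differentially expressed, with the direction pair matching the quadrant's
biology (promoter methylation represses; gene-body methylation tracks
positively with expression). Pairs with opposite gene direction are tallied as
discordant, everything else as unpaired — logged, not headline. Requiring
gene-level significance, rather than a mere fold-change sign, is the stricter
of the two defensible readings and the one implemented. Counts are reported
both as probes and as distinct genes, since a gene with several significant
promoter probes would otherwise be counted ambiguously.

Per-gene promoter Δβ is the median over the gene's significant promoter
probes, and the headline association statistic is the Pearson correlation of
this quantity with the gene's log2 fold change (at least 3 matched genes
required; constant axes are an error, not NA).

The enhancer stage is a deliberately simplified supervised pairing, not a
reimplementation of any published enhancer-linking tool: each significant
enhancer-flagged probe is paired with its `k_nearest` (default 10) genes
within `window` (default 500 kb) on the same chromosome; each candidate pair
is tested with a one-sided Wilcoxon rank-sum on the gene's log2 CPM between
groups, with the direction locked anti-concordant to the methylation change
(hypomethylated probes can only be linked to upregulated genes, hypermethylated
to downregulated); BH runs across all candidate pairs and pairs below `alpha`
are kept. Gene positions are not part of the probe annotation, so a gene's TSS
is proxied by the median position of its promoter probes (minimum probe
position when it has none) — adequate at a 500 kb window, and stated here
because it is an approximation.

## The synthetic generator

The generator exists so that every stage can be tested against a known answer.
Its defaults emulate the target study design: 10 tumors vs 4 normals, 2,000
probes and 2,000 genes with 10% planted effects per direction, |Δβ| = 0.6,
log2 fold change 2.

* **β model.** Baselines are drawn from a 50/50 mixture of a low Beta mode
  (mean ≈ 0.15) and a high mode (mean ≈ 0.85), matching typical array
  bimodality. Planted hyper probes start from the low mode and shift the tumor
  mean up by exactly `delta_effect`; hypo probes mirror this from the high
  mode. Baselines are truncated so the shifted mean stays within
  [0.02, 0.98], making the shift exact rather than clipped. Noise is Beta
  with concentration `beta_precision` (default 300, i.e. a per-sample SD of
  roughly 0.02 at mid-range means); `Inf` gives noiseless values for
  degenerate-limit tests.
* **Count model.** Gene baselines are log-normal (median 150 counts),
  library-size factors are log-uniform over a 3-fold range (so CPM
  normalization is non-trivial), counts are negative binomial with dispersion
  0.1 (typical bulk RNA-seq), and planted genes shift tumors by
  `lfc_effect` log2 units.
* **Linkage.** Planted methylation and expression effects are connected at
  the gene level: all promoter probes of a linked gene carry the same label,
  and each planted probe's mapped gene receives the concordant expression
  label with a per-quadrant probability (default 0.5 each for
  promoter-hypo/up, promoter-hyper/down, body-hyper/up, body-hypo/down and
  enhancer-hypo/up-nearest-gene). The evaluation ground truth for quadrant
  recovery is every probe–gene pair whose planted labels are consistent with
  a quadrant, however the gene acquired its label — this is the fair
  comparison for precision, since the pipeline cannot distinguish a linked
  gene from an independently planted one.
* **Geometry.** Gene loci sit on a deterministic grid (100 kb spacing, 100
  genes per chromosome, a configurable fraction on chrX to exercise the sex
  filter); promoter probes lie within 2 kb upstream of their TSS, body probes
  within 20 kb downstream, enhancer probes 20–60 kb from their anchor gene and
  other intergenic probes beyond. Positions are unique and strictly increasing
  per chromosome by construction.
* **Effects the generator does not model**: tumor-purity dilution of Δβ,
  probe-level technical artifacts (dye bias, batch), correlated probes within
  a region beyond the shared gene label, FFPE degradation, and outlier
  samples. Recovery results on synthetic data are therefore an upper bound on
  real-data performance; in particular, purity dilution in real tumors shrinks
  Δβ toward 0 and would cost sensitivity at the fixed 0.3 effect threshold.

All randomness flows from one base seed through named substreams (one per
generator stage), so adding a stage never perturbs the draws of earlier
stages, and two runs with the same configuration are bit-identical.

## Null calibration

The package's calibration tests permute the group labels and measure the
fraction of raw p-values below 0.05 among *truth-null* features. Planted
features are excluded deliberately: permuting labels over a mixture containing
genuinely shifted features does not produce a null — any imbalance between the
permuted groups leaves a real mean difference — so including them would
measure residual power, not test size. On null features the exact
2×3 test is strongly conservative (its discrete support at 10 vs 4 rarely
reaches p < 0.05), and the t-referenced NB Wald test sits at its nominal
level.

## Problem sizes and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | BH-adjusted significance level, both tests |
| `min_delta_beta` | 0.3 | minimum \|Δβ\| (unitless β difference) |
| `bin_edges` | 0.3, 0.7 | β state boundaries (closed outward) |
| `cpm_threshold` | 1 | CPM above which a gene is expressed (exclusive) |
| `expressed_fraction` | 0.8 | required fraction of one group (exclusive) |
| `enhancer_window` | 500 kb | maximum probe–gene distance |
| `enhancer_k` | 10 | nearest genes considered per probe |
| `n_probes`, `n_genes` | 2,000 | default synthetic study size |
| `delta_effect` | 0.6 | planted β shift |
| `lfc_effect` | 2 | planted log2 fold change |
| `beta_precision` | 300 | Beta noise concentration |
| `nb_dispersion` | 0.1 | NB dispersion of simulated counts |

The default synthetic sizes (2,000 × 2,000, 14 samples) were chosen so that a
full pipeline run, including two exact-test passes and per-gene GLMs, is a
matter of seconds while still leaving ~400 planted features per data type for
stable sensitivity and FDR estimates.

## Known limitations

* The exact 2×3 test conditions on both margins; with 14 samples its discrete
  null support makes it conservative, which costs power at probes whose β
  separation straddles a bin boundary. The Δβ filter, not the p-value, is
  usually the binding constraint in that regime.
* The NB Wald stand-in performs no dispersion shrinkage; at very low counts
  its method-of-moments dispersion is noisy, mitigated but not removed by the
  expression filter and the t reference.
* Quadrant analysis keys probes to genes through the manifest's single
  `gene_symbol`; probes annotated to multiple overlapping genes are outside
  the model.
* The enhancer stage tests marginal group differences per gene; it does not
  model probe–gene dosage relationships and cannot, by design, reproduce the
  pair counts of correlation-based enhancer tools.
* No region-level (DMR) calling, cell-type deconvolution, purity correction
  or batch adjustment; inputs are assumed normalized β values and raw counts.
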