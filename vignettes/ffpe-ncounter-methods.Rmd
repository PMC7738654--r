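---
title: "Methods: analysing degraded FFPE RNA counts from the nCounter platform"
author: "nCounterFFPE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing degraded FFPE RNA counts from the nCounter platform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nCounterFFPE)
```

# Scope and model

The package implements the analysis chain used for multiplexed
gene-expression panels run on degraded, formalin-fixed paraffin-embedded
(FFPE) RNA with the NanoString nCounter digital counter: background
estimation from negative-control probes, housekeeping-gene screening and
selection, housekeeping normalization, signal-to-noise detection filtering,
unpaired-t-test differential expression with a signed fold-change
convention, exact hypergeometric over-representation analysis, and
hierarchical-clustering / volcano reporting. The central container,
`NCounterSet`, extends `SummarizedExperiment`: rows are codeset probes with
a `CodeClass` (Endogenous, Housekeeping, Negative, Positive), columns are
samples with an optional case/control `Group`.

The guiding statistical concern is specific to FFPE: genuinely
low-expressed genes are indistinguishable from transcripts lost to
degradation, so the pipeline filters rather than models them. All QC
quantities (background threshold, housekeeping screen, signal-to-noise
ratio) are computed on **raw** counts; mixing a raw-count background with
normalized signal would be incoherent.

# Stage-by-stage definitions and defaults

## Background (`estimateBackground`)

For sample $s$ with negative-control counts $x_{1s},\dots,x_{ms}$
($m \ge 2$):
$$\theta_s = \bar x_s + 2\,\mathrm{SD}(x_{\cdot s}),$$
with the sample ($n-1$) standard deviation. Eight negatives is a small
sample, and the $n-1$ form is the common choice in nCounter practice; the
multiplier (default 2) is exposed. With all-zero negatives, $\theta_s = 0$
with a warning, and SNR degenerates to $\infty$/0 per cell.

## Housekeeping screening and selection (`screenHousekeeping`,
`genormStability`, `selectHkPanel`)

A housekeeping (HK) gene "close to background" must not enter
normalization. "Close" is quantified as failing
$\text{count} > k\,\theta_s$ (strict) in **every** sample, with $k = 3$ by
default — the same multiple as the detection cutoff, which is the least
arbitrary choice available; $k$ is a parameter. Failing genes are flagged,
never dropped from the matrix.

Two selection routes are provided, because practice uses both:

* **geNorm stability** for unsupervised overview analyses:
  $M_j = \operatorname{mean}_{k \ne j} \mathrm{SD}_s\!\left(\log_2 x_{js} -
  \log_2 x_{ks}\right)$, lower is more stable, with the classical iterative
  elimination (`genormRank`). $M$ requires at least 3 candidates; for 2 it
  is left undefined rather than reported as a meaningless 0.
* **Correlation-based panel selection** for DE normalization, emulating
  manual selection of a small panel with robust signal and good mutual
  correlation: among all `panelSize` (default 4) subsets of passing HK
  genes, the panel maximizing the minimum pairwise Pearson $r$ on
  $\log_2(\text{count}+1)$, subject to that minimum being $\ge$ `minR`
  (default 0.8). Ties break by lower mean geNorm $M$, then lexicographic
  gene names, so selection is deterministic.

Pearson $r$ is computed on $\log_2(x+1)$: the log scale stabilizes
variance, and the pseudocount handles zeros without branching.

## Normalization (`normalizeCounts`)

With $g_s$ the geometric mean of the panel's raw counts in sample $s$, the
scale factor is $f_s = \overline{g}/g_s$ (arithmetic mean of the $g_s$ as
reference), and all counts in $s$ are multiplied by $f_s$. The reference
only fixes the overall scale — any constant gives identical DE statistics —
and this form keeps counts near their familiar magnitude. The defining
fixed point (panel geometric means identical across samples afterwards) and
idempotence are asserted by tests. Downstream analysis uses
$\log_2(\text{normalized}+1)$; published analyses of this kind
log-transform normalized data without stating zero handling, and $+1$ is
the conventional choice.

## Detection (`scoreDetection`)

$\mathrm{SNR}_{gs} = \text{raw}_{gs}/\theta_s$; a gene is present when
$\mathrm{SNR} > 3$ (strict, the cutoff is quoted as ">3") in at least
`minFraction` (default 0.5) of the samples of at least one group
(`scope = "any_group"`). The aggregation rule is genuinely open — a
published "detected" count cannot be inverted to recover it — so it is a
parameter; the any-group default keeps group-specific genes (e.g. genes
expressed only in diseased tissue) alive, which an all-samples rule would
discard. Only Endogenous probes are filtered.

## Differential expression (`runDE`, `callDegs`)

Per detected gene, an unpaired t-test on $\log_2(\text{normalized}+1)$,
case vs control. Default is the pooled-variance (Student) test with
$df = n_1+n_2-2$ — the default behind the common "unpaired t-test" menu
item — with Welch available. Fold change derives from the difference of
log2 means, $\Delta$: linear ratio $R = 2^\Delta$, reported with the signed
convention $R$ if $R \ge 1$ else $-1/R$, so a halving is $-2.0$. Whether
published fold changes of this kind come from log-scale or linear-scale
means is usually unstated; both are implemented (`fcMode`), defaulting to
log-scale for consistency with the volcano and heatmap representations.
DEG calling is $|FC| \ge 1.5$ (inclusive) and $p < 0.05$ (strict),
uncorrected — multiple-testing correction is deliberately off by default to
prioritize sensitivity in small exploratory cohorts, with
Benjamini–Hochberg available as an annotation that never changes default
calls. Degenerate inputs are defined, not accidental: two equal constant
groups give $t=0, p=1$; unequal constant groups give $p=0$ with a
zero-variance flag (volcano capping handles the $-\log_{10} 0$).

## Enrichment (`ora`, `sharedTermNetwork`)

Exact one-sided hypergeometric upper tail,
$p = \sum_{i \ge k} \binom{K}{i}\binom{N-K}{n-i}/\binom{N}{n}$, computed
with `phyper`. The universe defaults to the **detected** genes: enrichment
background must be the set that could have been called, not the full
codeset (full-panel universe remains available by passing it explicitly).
Up- and down-regulated queries are always analysed separately. The
shared-annotation network is a transparent co-membership proxy (edge iff
two query genes share $\ge w$ sets, weight = count) standing in for
database-derived interaction networks, which require external retrieval;
it is labelled as such and makes no physical-interaction claim. A small
synthetic GMT (`inst/extdata/toy_immune.gmt`, toy terms over the simulated
gene namespace) ships for tests and end-to-end runs; real collections are
user inputs.

## Clustering and reporting (`clusterExpression`, `volcanoTable`)

Hierarchical clustering on Euclidean distance of per-gene z-scaled
$\log_2$ data ("equal variance for all genes"); constant genes become
zero rows and are flagged. Average linkage is the default — the distance
is the conventionally reported choice, the linkage rarely is, and average
is the common heatmap default; complete and Ward (ward.D2) are offered.
`stats::hclust` provides the (deterministic) agglomeration; merges are
verified against a brute-force oracle in the tests. Two clustering inputs
mirror common practice: an all-gene overview (geNorm-selected HK
normalization) and a DEG-rows heatmap; `runPipeline` clusters DEG rows.
Dendrograms are serialized as newick, heatmap matrices and volcano
coordinates ($x = \Delta$, $y = -\log_{10} p$) as TSV.

# The synthetic-data generator

`simulateCounterSet(simConfig())` draws counts as
$$\text{count}_{gs} \sim \mathrm{NB}\!\left(\mu = d_s\,b_g\,2^{\ell_g
\mathbb{1}[s \in \text{case}]} + \beta_s,\ \text{size} = 1/\phi\right)$$
with per-sample degradation (efficiency) $d_s$, per-gene baseline $b_g$,
planted log2 fold change $\ell_g$, per-sample background mean $\beta_s$
(negative probes have $\mu = \beta_s$ only), and dispersion $\phi$
(variance $\mu + \phi\mu^2$; $\phi = 0$ falls back to Poisson). Background
is **additive** — a hybridization noise floor — rather than
$\max(\text{signal}, \text{background})$, keeping SNR well defined;
degradation is a multiplicative per-sample efficiency, which housekeeping
normalization should remove exactly in expectation, making normalization
correctness a testable recovery problem. One RNG stream keyed by
`simConfig(seed=)` drives everything; identical configs are bit-identical.

Defaults are the study conditions the pipeline is exercised under:

| parameter | default | rationale |
|---|---|---|
| panel | 579 endogenous, 8 negative, 15 HK | immune-panel codeset composition |
| groups | 11 case vs 4 control | small archival cohort |
| baseline $\log_2 b_g$ | $N(9, 1.2^2)$ | robust signal well above background |
| HK baseline | $N(10, 0.5^2)$ | high and tight, as reference genes should be |
| dispersion $\phi$ | 0.02 | counting CV ≈ 14%, in line with typical nCounter replicate variability |
| background $\beta_s$ | $U(5, 15)$ counts | realistic negative-control magnitudes |
| degradation $d_s$ | $U(0.1, 1)$ | archival FFPE spans ~an order of magnitude of effective quality; this spread also makes between-sample signal dominate counting noise, so a 4-HK panel with pairwise $r$ in the high 0.8s–0.95s exists, matching reported practice |
| dropout fraction | 130/579 | expected detected count 449 of 579 |
| DE fractions | 48/579 up, 21/579 down | realistic DEG yield for this design |
| planted FCs | {1.5, 2, 2.5, 4, 6} | spanning the magnitude range such panels report |

Dropout genes get baselines capped so their expected SNR is $\le 1$ in
every sample: they emulate degradation-lost transcripts and must fail
detection. DE genes are drawn disjointly from dropout genes, since a
planted effect that cannot pass detection tests nothing.

What the generator does **not** emulate: fragment-length/RIN structure
beyond the scalar efficiency, probe-sequence effects, correlated gene
modules, batch/cartridge effects, or real biological covariance. Passing
tests therefore demonstrate the pipeline's correctness and calibration
under a clean, known-truth model of degraded counting data — not that any
particular biological dataset will reproduce published gene lists.

# Numerical and design notes

* **Strict vs inclusive boundaries** are taken literally from the
  conventional definitions: SNR cutoff strict ($>3$), HK screen strict,
  FC boundary inclusive ($\ge 1.5$), p boundary strict ($<0.05$).
* **Probe identity** is (class, name); accession is carried but never a
  key. Assembling lanes with mismatched or permuted probe lists is a hard
  error — count matrices are never silently reordered or deduplicated.
* **Raw-data sample exclusion** (vendor QC flags) is out of scope by
  design; the object model accepts any subset of lanes, so exclusion
  policy stays with the user.
* **Determinism.** Panel selection, DEG calling, clustering and the
  pipeline manifest are deterministic given config + seed; ties in panel
  selection resolve by stability then name.
* **Unsupervised clustering of all genes** is expected to be confounded by
  per-sample quality (degradation × background inflation is a competing
  axis of variation in FFPE data, and real studies show occasional samples
  clustering with the wrong group); the group-separation property is
  asserted on the DEG-row clustering, which is also what the pipeline
  reports.
* **Problem sizes in the test suite** (chosen as the package's own test
  design): full 602 × 15 datasets where shape matters; 20–60-gene panels
  for property loops; 2000 null genes for type-I calibration; 10–20 seeds
  for recovery/separation frequencies; exhaustive enumeration oracles up
  to $N = 12$ (hypergeometric), 6 genes (geNorm), 5 leaves (linkage).

# Known limitations

* The t-test on $\log_2(\text{NB}+1)$ values is an approximation; with 4
  controls its small-sample behaviour depends on the log-scale noise being
  near-normal, which holds at the default dispersion but degrades for very
  low counts (those are largely removed by the detection filter).
* Fold changes for genes near background are biased toward zero by the
  additive floor; the pipeline filters rather than background-subtracts,
  matching field practice for this platform.
* The shared-annotation network is a co-annotation proxy, not an
  interaction database.
* geNorm pairwise-variation panel-size optimization ($V_{n/n+1}$) is not
  implemented; panel size is fixed by the user (default 4).

```{r session}
sessionInfo()
```
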