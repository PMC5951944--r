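---
title: "Detecting bidirectional eRNA loci from CAGE data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bidirectional eRNA loci from CAGE data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bidiCAGE)
library(data.table)
```

`bidiCAGE` detects candidate enhancer RNA (eRNA) loci in two-condition
CAGE experiments by finding pairs of divergent transcription start site
(TSS) clusters that both respond strongly to the stimulus. This vignette
explains the models behind each stage, the tunable parameters and their
defaults, what the synthetic data generator does and does not emulate, and
the design decisions taken where several reasonable choices existed.

## Coordinates and input formats

Everything internal is 0-based, half-open. CTSS input is BED6 with the tag
count in the score column, one row per (position, strand); BED coordinates
pass through unchanged, GTF coordinates are converted (+1, inclusive →
half-open) at the boundary, so no off-by-one can accumulate. A minus-strand
transcript's TSS is its high coordinate minus one. The CTSS dialect is a
package convention (the on-disk format of CTSS tables is not standardized);
raw integer counts are assumed, not normalized scores.

## Consensus clustering

Per-sample tables are merged over the union of positions. Positions whose
pooled count, scaled by the total pooled library
(`pooled TPM = pooled count / sum of library sizes * 1e6` — the pooling
convention is ours), falls below `min_pooled_tpm = 0.5` are dropped, and
the rest are single-linkage clustered per chromosome and strand: two
retained positions join one cluster iff their gap is at most
`max_gap_cluster = 20` bp. 20 bp is the conventional distance-clustering
default for CAGE promoter calling; the floor of 0.5 TPM removes
sporadic single-tag positions while keeping real promoters, whose pooled
signal is orders of magnitude higher. Cluster counts are exact element-wise
sums of member counts (conservation is asserted by tests), and the cluster
anchor for all downstream distances is the *dominant position* — the member
with maximal pooled count, ties broken toward the 5′-most position on the
cluster's strand. The dominant CTSS is the best single-nucleotide TSS
estimate; span midpoints blur with cluster width.

## Differential expression

The count model is negative binomial with variance $\mu + \phi\mu^2$.

**Normalization.** Trimmed-mean-of-M-values (TMM) factors: the reference is
the sample whose upper-quartile relative expression is closest to the mean;
for every other sample, gene-wise log2 ratios M and average abundances A
are formed over rows nonzero in both, the top and bottom 30% by M and 5% by
A are trimmed, and the factor is 2 to the precision-weighted mean of the
remaining M (inverse delta-method variances as weights), rescaled to
geometric mean one. The implementation agrees with the reference
implementation in `edgeR` to six decimals on random matrices (a test
asserts this).

**Equalizing library sizes.** The conditional test requires exchangeable
library sizes, so counts are first quantile-adjusted to the geometric-mean
effective library: the mid-P cumulative probability of the observed count
under its fitted NB is mapped through the quantile function of a
moment-matched gamma (a continuous interpolation of the discrete NB
quantiles) at the target mean. Samples whose effective libraries already
agree to within $10^{-9}$ relative skip the adjustment, which keeps small
exact examples exact.

**Dispersion.** The common $\phi$ maximizes the summed conditional NB
log-likelihood over clusters (conditioning on per-group row totals after
equalization), optimized on $\log\phi$ over $[10^{-6}, 10]$, with two
equalize–maximize iterations since the adjustment itself depends on
$\phi$. An optional tagwise mode maximizes each row's conditional
likelihood plus `prior_df = 10` pseudo-rows of the average likelihood
curve, shrinking noisy per-row estimates toward the common value. All-flat
matrices return the lower bound with a warning. On simulated data with
known $\phi = 0.1$ (2000 clusters, 4+4 samples) the estimate lands within
[0.08, 0.12].

**Exact test.** Conditional on the total pseudo-count $t$ of a cluster,
the probability that group 1 (with $n_1$ samples) holds $a$ tags is
negative hypergeometric with weights
$\binom{a + n_1/\phi - 1}{a}\binom{t - a + n_2/\phi - 1}{t-a}$ —
notably free of $\mu$ — and the two-sided p-value sums all splits whose
probability does not exceed the observed one. As $\phi \to 0$ this is the
binomial split distribution (0 of 10 tags at equal libraries gives
$p = 2/1024$). Enumeration is exact for totals up to $10^5$; above that
the range is truncated to retain at least $1 - 10^{-12}$ of the
conditional mass. BH-FDR is the textbook step-up, and the
increased/decreased split takes significant rows at FDR < 0.1 by the sign
of the fold change. The log2 fold change adds a pseudo-count of 0.25 (on
the normalized-TPM scale) to each condition mean to avoid infinities.

## Bidirectional pairing and classification

Candidate pairs are a minus-strand cluster $m$ and a plus-strand cluster
$p$ on the same chromosome with
$0 \le \mathrm{anchor}(p) - \mathrm{anchor}(m) \le 300$ bp — divergent
geometry, with transcription running outward. Pairs are accepted greedily
in ascending gap order with deterministic tie-breaks by (chromosome, minus
anchor, plus anchor); each cluster joins at most one locus. Greedy (rather
than optimum-cardinality) matching is simple, order-invariant, and in
practice optimal here because clusters are non-overlapping and sparse; a
test compares it against an optimal bipartite matching oracle.

A strand of a locus passes the response screen when its
stimulated/control ratio of condition-mean normalized TPM (pseudo-count
0.25) exceeds `min_fold = 10` *and* its cluster FDR is below 0.1. The
condition means use TMM-effective library sizes rather than raw library
sizes: strongly responding loci inflate the stimulated libraries, and raw
TPM would deflate every fold estimate by exactly that inflation;
correcting composition bias is what TMM is for. The screen's ">10"
threshold is interpreted as a fold ratio; an absolute-difference mode
(`response_mode = "difference"`) is provided behind a switch since a
difference reading is also defensible. Both-strands-pass loci are
`bidirectional`, one-strand loci `plus_only`/`minus_only`, the rest
`none`; `none` loci are retained (flagged) so the candidate count and the
Venn counts both derive from one table.

## Annotation

The locus midpoint (for single clusters, the dominant position) is
annotated with the nearest protein-coding transcript TSS over *all*
transcripts, not one canonical TSS per gene. The signed distance is
gene-oriented: $d = \mathrm{anchor} - \mathrm{tss}$ for + genes and
$\mathrm{tss} - \mathrm{anchor}$ for − genes, so negative is upstream of
the gene. Ties in $|d|$ break toward the lexicographically smallest gene
id. Categories follow the conventional peak-annotation hierarchy, fixed
and documented since several orders are seen in the wild: promoter within
±3000 bp of any TSS (sub-binned at 1 and 2 kb), then 5′ UTR, 3′ UTR,
exon, intron, downstream (≤3 kb past the 3′ end in gene orientation),
else distal intergenic. UTRs are exon segments outside the CDS span;
transcripts without CDS contribute no UTR categories. Enhancer-set overlap
is a half-open point-in-interval test.

## The synthetic study

`sim_config()` defaults define the study conditions: two 5-Mb
chromosomes, 200 non-overlapping protein-coding gene models, 60 divergent
enhancers (40 responsive on both strands at fold 12, 10 on one strand, 10
silent) with TSS gaps uniform on [20, 280] bp and a 15% intronic fraction,
enhancer baseline mean 50 tags/strand/sample, NB dispersion
$\phi = 0.05$, four replicates per condition, per-sample library factors
uniform on [0.85, 1.15], 500 background noise CTSSs per chromosome
(count 1–2, in a single random sample), seed 20180514. Counts are drawn
once per element strand and sample and scattered multinomially over 1–5
adjacent positions so clustering is exercised non-trivially.

Values the study conditions leave open were fixed once on realism grounds:
promoter baseline means are lognormal (meanlog $\log 800$, sdlog 1.5),
matching the several-orders-of-magnitude dynamic range of real CAGE
promoters and producing libraries of a few hundred thousand tags, which
keeps count-1 noise positions below the 0.5 pooled-TPM floor; 20% of
promoters respond at fold 3 (half up, half down), exercising the
increased/decreased split while staying clear of the fold-10 eRNA screen.

The generator emulates the statistical structure the analysis relies on —
replicate NB counts with shared means, divergent geometry, planted
responders, sparse noise — and *not* read-level artifacts: no mappability
or GC bias, no splicing, no promoter shape, no tag-cluster width
distribution. Passing recovery tests therefore demonstrates correctness of
the pipeline's inference on its assumed model, not robustness to mapping
artifacts in real libraries.

## What desk scale does to the fold screen

Two deliberate consequences of the study conditions are worth deriving,
because they dominate the end-to-end recovery numbers that
`analysis/03_score_recovery.R` and `scripts/acceptance.R` report.

*Sampling noise of the fold estimate.* A strand with baseline mean 50 and
true fold 12 at $\phi = 0.05$ has per-sample count CV
$\sqrt{1/\mu + \phi} \approx 0.23$–0.27; with four replicates per arm the
log fold-ratio estimator has standard deviation
$\approx \sqrt{(0.23^2 + 0.27^2)/4} \approx 0.17$, while the screen's
margin is only $\ln(12/10) \approx 0.18$. A single strand therefore passes
the fold-10 screen with probability near $\Phi(1.05) \approx 0.85$, and a
locus needs both strands to pass, i.e. roughly 0.72 even under oracle
normalization. Fold-threshold screens this close to the effect size are
intrinsically noisy at replicate counts of four.

*Composition bias.* The planted responders are a large fraction of these
small libraries: the stimulated libraries are ~35% deeper purely from
planted signal, and the one-directionally responding rows are ~a third of
the rows usable by TMM (nonzero in both samples of a pair) — beyond the
30% trim. TMM therefore cannot see the shift (the factors match `edgeR`'s
on the same matrix; both are ≈ 1), observed folds center near
$12/1.3 \approx 9$, and most planted loci fail the screen. On real-scale
data (hundreds of thousands of clusters, a few percent DE) TMM removes
this bias; at desk scale it is a known, documented limitation of the
conditions, not of the implementation — the unit tests verify each
statistical component against independent oracles, and the recovery
scripts print the realized sensitivity and precision.

## Numerical and testing choices

Problem sizes were chosen to keep the whole suite interactive: the
end-to-end study is ~2000 CTSS positions and ~600 clusters; oracle grids
enumerate all splits with totals up to 60 at three dispersions; clustering
is checked against a connected-component oracle on 200 random tables of up
to 1000 positions; null FDR calibration uses 20 simulations of 2000
clusters. Determinism is part of the contract: datasets and pipeline
outputs are byte-identical under a fixed seed, verified by hashing.

Known limitations: two-group designs only (no covariates, no GLM path);
no promoter-shape or directionality-balance statistics; enhancer-set
overlap is a boolean flag, with no robust-vs-permissive grading; the
greedy pairing contract can in principle return fewer loci than an
optimal matching, though tests have not observed it on non-overlapping
clusters.
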