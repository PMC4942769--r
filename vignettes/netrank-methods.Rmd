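---
title: "netrank: network-ranked biomarkers from multi-condition expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netrank: network-ranked biomarkers from multi-condition expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netrank)
```

## The problem

Biomarkers discovered in manipulated animal experiments often fail to
replicate in human cohorts, even when the genes themselves are conserved.
One reason is that per-gene differential expression (DE) mixes two kinds of
signal: genes genuinely wired into the disease's regulatory response, and
genes that merely respond to the particulars of the training experiment
(anaesthesia, vehicle injections, time points). The second kind does not
transfer.

`netrank` implements a network alternative. Given paired miRNA and mRNA
expression profiles from a multi-condition training experiment, it

1. selects differentially expressed mRNAs by one-way ANOVA across the
   experimental conditions,
2. links every miRNA to every selected mRNA whose expression is
   *significantly negatively* correlated with it (miRNAs predominantly
   repress their targets), weighting each edge by $|r|$,
3. scores all nodes of this weighted bipartite network with PageRank and
   ranks mRNAs and miRNAs separately, and
4. takes the top-ranked mRNAs as the candidate biomarker panel, to be
   validated on independent case/control cohorts by two-cluster
   average-linkage hierarchical clustering.

The premise is that mRNAs that sit centrally in the miRNA-mRNA
co-regulation structure — hub genes — reflect the regulatory network
itself, which is more stable across species and platforms than the
expression level of any individual gene.

## Model and procedure

**ANOVA filter.** For each mRNA a one-way fixed-effects ANOVA F-test across
the condition groups is computed row-wise (the multi-factor design is
treated as unordered groups); features with $p \le \alpha$ (inclusive,
default $\alpha = 0.05$) are retained. If a feature's within-group variance
is numerically zero in every group, $p$ is defined as 0 when the group
means differ and 1 otherwise; such rows are counted and reported.

**Edges.** For each (miRNA, mRNA) pair, Pearson's
$r = \mathrm{cov}(x, y) / (s_x s_y)$ is computed across all training
samples pooled, with the usual two-sided test
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ degrees of freedom. Pairs with
$r < 0$ and $p \le \alpha$ become edges of weight $|r|$. All available
miRNAs participate regardless of their own ANOVA status; no
multiple-testing correction is applied to edge p-values — the edge test is
a screening rule, not an inferential claim, and correcting it would change
the network density, not the ranking principle. Pairs in which either
profile is constant are skipped and counted. Correlations are computed
pooled across all samples because pooling is the only choice that yields a
single network from a multi-condition design; the cost of pooling is
discussed under *Limitations*.

**PageRank.** The network is undirected (a correlation has no natural
direction), so each edge conducts score both ways, in proportion to its
weight relative to the total weight incident to the sending node. With
damping $d$ and $N$ nodes, the score vector is iterated from the uniform
vector as $s \leftarrow (1-d)/N + d\,P^\top s$ until the L1 change falls
below the tolerance. Defaults: $d = 0.85$ (the canonical damping of the
algorithm and of common graph libraries), tolerance $10^{-10}$, at most
1000 iterations. The tolerance is far below score gaps that could reorder
a top-100 list in practice; because nodes exist only through edges, there
are no dangling nodes and the scores sum to exactly one. A dense
linear-solve oracle and an independent graph-library implementation verify
the iteration in the test suite.

**Validation.** A cohort is median-normalized (each sample shifted so all
sample medians agree), the panel genes are z-scored, samples are clustered
by average-linkage agglomeration on Euclidean distances (correlation
distance is available behind a flag), and the dendrogram is cut at the
last merge into exactly two clusters. Accuracy is the better of the two
cluster-to-group assignments, so it is at least 0.5 and invariant to label
swaps; the misclassified samples under the best assignment are reported.
Whether to z-score before the distance computation is a genuine choice —
heatmap tools scale rows for display only — but without it the clustering
would be dominated by whichever panel gene has the largest variance, so
z-scoring is the default here. Genes missing from a cohort are dropped
with a warning rather than imputed.

**DE baseline.** The comparison ranking orders training mRNAs by the same
ANOVA p-value used by the filter (ties broken by gene id). The contrast a
practitioner would use for a DE baseline on a six-condition design is not
uniquely defined; re-using the filter statistic is the choice that makes
the two rankings differ *only* in the network step, which is the
comparison of interest.

## The synthetic benchmark

`synthetic_config()` describes a training experiment of 6 conditions × 4
replicates (50 miRNAs, 500 mRNAs) with three planted gene classes:

* **Hubs** (10): each repressed, with strength `beta = 0.8`, by a module of
  8 regulator miRNAs; hub expression is the negative weighted sum of its
  regulators' signals plus noise.
* **Training-specific decoys** (20% of non-hub genes): genes with their own
  independent per-condition shifts. They are strongly differentially
  expressed in training but *exchangeable* between the groups of any
  validation cohort — the false-transfer failure mode of the DE baseline.
* **Background genes**: pure noise.

miRNAs carry per-condition shifts of sd `condition_effect = 2.0` and
replicate noise of sd `sigma = 1.0`. Validation cohorts (20 case/20
control) shift only the hub genes, by `cohort_hub_shift` (default 2.0, in
noise-sd units; the sign per hub is part of the planted truth), so only
hubs replicate as informative.

**Why regulator modules are co-expressed.** If the 8 regulators of a hub
were fully independent, the hub — an average of eight signals — could
correlate with each individual regulator by at most
$1/\sqrt{8} \approx 0.35$ in magnitude. With only six conditions, a
decoy's random condition profile aligns with condition-structured miRNAs
with a correlation spread of similar size ($\approx 0.36$ sd at $n = 24$
pooled samples), so true regulation would be statistically
indistinguishable from condition-level coincidence and no ranking method
could recover the hubs. Real miRNA clusters are frequently co-transcribed
from shared promoters or polycistrons, so the generator models each hub's
regulators as a module sharing a common expression program (condition
response plus sample-level covariation) with within-module correlation
`mirna_module_cor = 0.7`; every miRNA keeps the same marginal distribution
(shift sd `condition_effect`, noise sd `sigma`), and `mirna_module_cor = 0`
recovers fully independent regulators. With the default cohesion the true
hub-regulator correlation is about
$\sqrt{(1+7\rho)/8} \approx 0.86$.

Even so, recovery is intentionally not trivial: with six condition-level
degrees of freedom and roughly a hundred strongly condition-shifted
decoys, chance anti-alignments between a decoy and a regulator module
occur regularly and mimic hub connectivity. On the default configuration
about two thirds of the top-10 PageRank mRNAs are true hubs (averaged
over seeds); the residual confusion is a property of small multi-condition
designs under pooled correlation testing, not of the implementation, and
the same anticonservativeness affects any real dataset with this layout.

**Reproducibility.** One seed drives a documented draw order (identities,
baselines, module programs, miRNA components, mRNA noise, decoy shifts);
identical configuration and seed give bit-identical matrices. Cohorts take
their own seed so several cohorts can be drawn against one training set.

## What the tests show (and what they do not)

The test suite verifies, at desk scale: exact agreement of the Pearson,
correlation-test and ANOVA statistics with brute-force and quadrature
oracles; agreement of the power iteration with a dense stationary solve on
hundreds of random weighted bipartite graphs; calibration of the edge rate
to $\alpha/2$ on structure-free data (50 replicates of the full design);
and planted-structure recovery plus the network-versus-DE accuracy-curve
comparison over 20 simulation replicates each (problem sizes: 50 × 500
features, 24 training samples, 40-sample cohorts, panel sizes 2–100).
`scripts/acceptance.R` recomputes the same quantities from scratch.

The generator emulates the *statistical* structure the method assumes —
negative regulation, hub connectivity, training-specific confounding — not
microarray physics: no probe-level artefacts, saturation, batch effects or
heavy-tailed noise, and regulation is linear-Gaussian. Passing tests
therefore demonstrate correctness of the algorithms and the claimed
qualitative behaviour under the assumed model; they do not certify
performance on any particular real dataset.

## Numerical choices and degenerate inputs

* Median normalization equalizes column medians at the grand median of the
  original column medians (an additive shift on the log scale; a
  multiplicative reading on the raw scale is equivalent).
* Lowess normalization regresses each sample's deviation from the
  row-median pseudo-array on the pairwise mean intensity, with span 2/3
  and 3 robustness iterations; under 10 features it falls back to median
  normalization with a warning.
* Features with missing values are dropped at read time (no imputation).
* Exact score ties in rankings break lexicographically by identifier;
  constant panel genes contribute a zero z-score row rather than being
  silently removed; an empty network or an empty feature intersection is a
  hard error carrying diagnostics.
* Raw-scale input can be log2(x+1)-transformed at read time via a flag.

## Limitations

* Pooling samples across conditions makes the correlation test
  anticonservative for condition-structured but unrelated feature pairs
  (replicates within a condition are not independent evidence). This
  inflates the network with condition-level coincidences in any
  multi-condition design with few conditions; the null-calibration checks
  therefore use structure-free data, and rankings from small designs
  should be read as screening output.
* With few truly replicating genes, clustering accuracy necessarily decays
  as the panel grows past them; accuracy-versus-k curves should be read
  jointly with panel content, not as a single summary number.
* The DE baseline is one reasonable choice among several; conclusions
  about "DE" generalize only to per-gene rankings of the same kind.
* miRNA rankings are produced but not validated by clustering, mirroring
  the practical difficulty of assaying miRNA panels across platforms.
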