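---
title: "Calling genomic sub-compartments from inter-chromosomal Hi-C contacts"
author: "subHiC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling genomic sub-compartments from inter-chromosomal Hi-C contacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subHiC)
```

## The model

Sub-compartments are groups of genomic bins that contact each other
across chromosomes more often than expected and share chromatin state.
`subHiC` treats their discovery as a weighted-graph clustering problem.
The genome is tiled into fixed-width bins (default 100 kb; 0-based
half-open coordinates everywhere on disk). The normalized
inter-chromosomal contact map defines an undirected weighted graph: one
node per bin, an edge between any two bins on different chromosomes with
weight $w_{ij}$ equal to their normalized contact count. Intra-chromosomal
contacts are excluded by design — their strong distance decay would
dominate any clustering signal, whereas inter-chromosomal contact
frequency directly reflects co-location in the nucleus. Upstream matrix
balancing (KR/ICE) is assumed already done; the package accepts any
nonnegative weights and never renormalizes.

### Graph embedding

Nodes are mapped to vectors by LINE-style embedding with two notions of
proximity:

* **First order.** An edge is modeled as
  $p_1(v_i, v_j) = \sigma(u_i^\top u_j)$, and the embedding minimizes
  $O_1 = -\sum_{(i,j) \in E} w_{ij} \log p_1(v_i, v_j)$, the KL
  divergence (up to constants) between $p_1$ and the empirical edge
  distribution $w_{ij}/W$.
* **Second order.** Each node also has a context vector $u'_i$; the
  probability of observing context $j$ from node $i$ is the softmax
  $p_2(v_j \mid v_i) = \exp(u'^\top_j u_i) / \sum_k \exp(u'^\top_k u_i)$,
  and the objective $O_2 = -\sum_{(i,j)} w_{ij} \log p_2(v_j \mid v_i)$
  (undirected edges expanded to both directions; the empirical target is
  $w_{ij}/d_i$ with $d_i$ the node strength). Nodes with similar contact
  neighborhoods embed nearby even without a direct edge.

Training uses stochastic gradient descent over weighted edge draws
(alias tables give O(1) draws proportional to $w_{ij}/W$) with negative
sampling: each positive draw is contrasted with `negative` noise nodes
drawn proportional to $d_i^{3/4}$, the standard word2vec/LINE noise
distribution (the source is silent on this choice). **Joint mode**
(default) flips a Bernoulli($\alpha$) coin per draw and performs a
second-order update with probability $\alpha$, else first-order, which
optimizes $O_3 = (1-\alpha) O_1 + \alpha O_2$ in expectation while
keeping per-sample cost constant. **Separate mode** trains each order at
full `dim` and concatenates the row-wise L2-normalized halves
(normalization prevents one order from dominating Euclidean k-means
downstream; the combination rule is otherwise unconstrained by the
method's description).

### Clustering and model selection

k-means (Lloyd iterations from k-means++ seeds, best inertia of `nInit =
10` restarts, ties to the earliest restart) clusters the vertex vectors.
Bins with zero inter-chromosomal degree cannot be embedded and are
reported `NA`. The number of sub-compartments defaults to 5 — the scale
at which sub-compartments are usually annotated and compared — but can be
selected by the gap statistic: within-cluster dispersion is compared
against `B` uniform reference sets drawn in the PCA-aligned bounding box
of the embedding (`cluster::clusGap`, `spaceH0 = "scaledPCA"`), and the
smallest $k$ with $\mathrm{gap}(k) \ge \mathrm{gap}(k+1) - s_{k+1}$ wins
(Tibshirani's original rule; the exact variant used elsewhere is not
specified, so the canonical one is used and named). Because the
reference box is PCA-aligned, the choice of $k$ is invariant to rigid
rotations of the embedding.

Cluster numbering from k-means is arbitrary, so `relabelAssignment()`
reorders labels by decreasing mean of any per-bin signal (gene density,
accessibility, ...), making C1 the most open sub-compartment; ties break
toward the larger cluster. Without an external annotation to match, this
signal-based convention is the reproducible choice.

## Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| `resolution` | 100 000 | bp | bin width; sub-compartment resolution is configurable |
| `dim` | 100 | — | embedding size per order; 32 suffices at desk scale |
| `negative` | 5 | draws | noise nodes per positive sample |
| `samples` | 25 | millions | edge draws; scale with the edge count (see below) |
| `alpha` | 0.5 | — | joint-mode weight of the second-order objective |
| `lr` | 0.025 | — | initial SGD rate, decays linearly to `lr/100` |
| `k` | 5 | — | number of sub-compartments, or gap-selected |
| `minPet` | 5 | PETs | ChIA-PET loop support threshold (inclusive) |

## Numerical choices

* **Initialization.** Vertex vectors start uniform in
  $(-0.5/d,\,0.5/d)$; context vectors start at zero (so the initial
  second-order softmax is exactly uniform, a useful analytic anchor for
  tests).
* **Learning-rate schedule.** $\rho_t = \rho_0 (1 - 0.99\,t/T)$; neither
  the schedule nor the initialization is prescribed by the method's
  description, so the ecosystem-standard choices are used and flagged as
  such.
* **Determinism.** Training runs single-threaded on a self-contained
  splitmix64/xorshift128+ RNG; the same seed gives bit-identical
  embeddings independent of R's RNG state. A `workers` argument is
  accepted for interface compatibility, but asynchronous multi-worker
  updates (which trade bit-reproducibility for speed) are not
  implemented.
* **Sampling budget and saturation.** The draw count should scale with
  the edge count (the 25 M default matches genome-scale graphs with
  millions of edges; package tests use 50 k–1 M draws for graphs of
  325–24 000 edges). Negative sampling optimizes a surrogate whose
  optimum is *not* the exact softmax maximum likelihood: with heavy
  over-sampling relative to graph size, dot products saturate and the
  exact objectives $O_1$/$O_2$ pass through a minimum and rise again,
  even as cluster separation keeps improving. Objective-decrease checks
  therefore use budgets in the pre-saturation regime (~150 draws per
  edge).
* **Overflow safety.** All sigmoids clamp their argument to $\pm 35$;
  softmax rows subtract their maximum before exponentiation.
* **Degenerate inputs.** Zero/negative/NaN contact weights are dropped
  (counted, with a warning); duplicate records in either orientation are
  summed, tolerating symmetric matrix dumps; graphs with fewer than two
  connected nodes refuse to embed; an all-identical embedding refuses the
  gap statistic; a 50/50 anchor overlap is unassigned (strict majority);
  a zero inter-loop count reports an infinite ratio with an explicit
  flag rather than an error.

## Evaluation metrics

Silhouette uses Euclidean distance with $s_i = (b_i - a_i)/\max(a_i,
b_i)$; singletons score 0. The Davies–Bouldin index here is the
*pairwise* variant: $d_i$ is the mean distance over all point pairs
within cluster $i$ and $d_{ij}$ the mean over all between-cluster pairs —
this differs from the classic centroid-based index, and the wording
"distance between all pairs between clusters" is read as the mean over
between-cluster pairs (a documented deviation risk). Network topology of
each sub-compartment's induced subgraph is summarized by closeness with
Wasserman–Faust component scaling (intra-compartment subgraphs can be
disconnected), betweenness (unnormalized, each unordered pair counted
once; an option divides by $(n-1)(n-2)/2$), and the Barrat weighted
clustering coefficient, which reduces to the plain closed-triplet ratio
at unit weights. Whether shortest paths should treat contact weights as
distances is not decidable from the method's description, so both modes
ship: `hop` (unweighted, the common library default) and `invweight`
(length $1/w_{ij}$, strong contacts are short). Mann–Whitney comparisons
use the exact null for tie-free samples up to $n = 8$ and the
tie-corrected normal approximation otherwise; Fisher tests on loop
count tables are exact (hypergeometric).

ChIA-PET loops validate an annotation externally: after filtering
(intra-chromosomal, $\ge$ 5 PETs), each anchor is assigned to the label
covering a strict majority of its base pairs — computed against the
union of same-label bins, since anchors may span bin boundaries — and
loops with an unassignable anchor are excluded from numerator and
denominator alike. The loop-compartment matrix $M$, its symmetrization
$M_{sym} = M + M^\top$ and the normalized $M_{norm}$ are all reported;
no cross-method display normalization is applied.

For expression, genes expressed in at least one replicate are
represented by their TSS; all same-chromosome TSS pairs within a
distance ceiling (100 kb steps up to 10 Mb) are labeled intra or inter
by their bins' labels, Spearman correlation is computed per pair across
replicates, and group means and their ratio are reported. The p < 0.05
significance filter mirrors the original analysis protocol, but with six
replicates the exact Spearman p-value is so coarse that only
$|\rho| \gtrsim 0.89$ passes — the filter censors the very contrast it
is meant to sharpen — so the unfiltered means are always reported
alongside and are what the package's own validation thresholds use.

## What the simulator does and does not emulate

The planted-partition generator reproduces the statistical structure the
method relies on, with known truth at every stage:

* **Contacts.** Each bin draws a latent label independently (every
  sub-compartment spans all chromosomes, as real ones do); each
  inter-chromosomal pair draws Poisson($\mu_{in}$) within a compartment
  and Poisson($\mu_{out}$) between, zeros omitted. Defaults — 6
  chromosomes × 40 bins at 100 kb, $K = 5$, $\mu_{in} = 20$,
  $\mu_{out} = 2$ — are the package's reference study conditions.
  Real Hi-C counts are overdispersed; a negative-binomial mode
  (`dispersion`) exists, but the Poisson default is kept because only
  the block structure matters for recovery.
* **Loops.** With probability `pIntra` (default 0.8) both anchors come
  from same-label bins of one chromosome, otherwise from different
  labels; anchors are centered in bins, PET counts are shifted
  geometric.
* **Signal.** Per-bin Gaussian around a per-label effect, clipped at 0.
* **Expression.** Per replicate, one co-expression factor per
  (compartment, chromosome) — compartment co-regulation acting within its
  chromosomal neighborhood — plus a global batch factor (sd 2) shared by
  all genes, mimicking depth/batch variation between RNA-seq replicates.
  The batch factor keeps the baseline pair correlation solidly positive,
  which matters because the intra/inter *ratio* of mean correlations is
  only a stable statistic when its denominator is bounded away from
  zero; drawing factors per chromosome rather than genome-wide gives the
  inter-compartment mean $K(K-1)/2 \times$ `nChroms` independent
  factor-correlation realizations to average over instead of 10.

Not emulated: distance-dependent intra-chromosomal contact decay
(intra-chromosomal analysis is out of scope), chromosome territories,
copy-number and mappability artifacts, overdispersion by default, and
any coupling between contact strength and signal beyond the shared
labels. Passing the planted-partition tests therefore demonstrates that
the pipeline recovers block structure planted in inter-chromosomal
contacts at realistic signal-to-noise — not that real Hi-C data meet
these assumptions.

## Validation workloads

The test suite and `scripts/acceptance.R` run entirely on simulated
data at sizes chosen to exercise each property well inside a desktop
budget: 240-bin graphs (~24 000 edges) with 1 M draws for
planted-partition recovery over 5 seeds; a 30-bin fixture with 50 k
draws for exact-objective decrease; 100 randomized instances for
gradient/finite-difference agreement; graphs and point sets of ≤ 15
nodes against brute-force oracles for every evaluation metric; 10-seed
gap-statistic recovery of 3 well-separated Gaussian blobs; 2 000
simulated loops and 400-gene expression tables for the external and
functional checks. Genome-scale runs only change `samples` and `dim`.

## Known limitations

* Bins with no inter-chromosomal contact are unassignable (`NA`); no
  low-coverage filter beyond zero degree is applied, since none is
  prescribed.
* The embedding is stochastic: different seeds give different (rotated /
  permuted) embeddings, and cluster numbering is only meaningful after
  signal-based relabeling.
* `.hic`/`.cool` containers are not parsed; inputs are text triplets
  plus chrom.sizes.
* Single-threaded training; genome-scale embeddings (25 M draws,
  dim 100) take minutes, not seconds.
* The gap statistic inherits the usual caveat that well-separated
  sub-structure within a compartment can pull $k$ upward; the default
  fixed $k = 5$ sidesteps this for comparative work.
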