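# subHiC

Genomic **sub-compartment** prediction from normalized inter-chromosomal
Hi-C contacts, by graph embedding and k-means clustering — together with
the structural, loop-based and functional machinery needed to judge the
resulting annotation.

## The problem and the method

Interphase chromatin segregates into spatial neighborhoods beyond the
coarse A/B compartment division: *sub-compartments*, groups of genomic
bins that preferentially contact each other across chromosomes and share
chromatin state. `subHiC` calls sub-compartments directly from the
inter-chromosomal contact map:

1. **Graph construction.** The genome is tiled into fixed-resolution bins
   (default 100 kb). An undirected weighted graph `G = [V, E]` is built
   with one node per bin and an edge for every pair of bins on *different*
   chromosomes, weighted by the normalized Hi-C contact count `w_ij`.
2. **LINE embedding.** Nodes are projected into `R^d` by optimizing
   first-order proximity (edge probability
   `p1(v_i, v_j) = σ(u_i · u_j)`, objective
   `O1 = −Σ_(i,j)∈E w_ij log p1`) and second-order proximity (context
   softmax `p2(v_j | v_i) = exp(u'_j · u_i) / Σ_k exp(u'_k · u_i)`,
   objective `O2 = −Σ w_ij log p2`), trained by negative-sampling
   stochastic gradient descent over weighted edge draws (alias method).
   Joint mode optimizes `O3 = (1−α) O1 + α O2`; separate mode trains both
   orders independently and concatenates the L2-normalized vectors.
   Defaults: `d = 100`, 5 negative samples, 25 million edge draws,
   `α = 0.5`.
3. **Clustering.** Euclidean k-means (k-means++ seeding, best of 10
   restarts) over the node vectors yields labels `C1..Ck`; bins with no
   inter-chromosomal contact are `NA`. `k` may be fixed (default 5) or
   chosen by the Tibshirani gap statistic against PCA-aligned uniform
   references. Labels can be reordered by any per-bin signal so that C1
   is the most "open" sub-compartment.

The package also implements the downstream evaluation toolkit:

- **Structural:** per-bin silhouette `s_i = (b_i − a_i)/max(a_i, b_i)`, a
  pairwise Davies–Bouldin index `DBI = (1/k) Σ_i max_j (d_i + d_j)/d_ij`
  (mean pairwise within- and between-cluster distances), and
  intra-sub-compartment network topology — Wasserman–Faust closeness,
  betweenness, Barrat weighted clustering coefficient — with Mann–Whitney
  comparison between two annotations.
- **ChIA-PET validation:** BEDPE loop filtering (intra-chromosomal,
  ≥ 5 PETs), anchor → sub-compartment assignment by strict majority
  (> 50 %) overlap, loop-compartment matrices `M`, `M_sym = M + Mᵀ`,
  `M_norm = M_sym / ΣM_sym`, intra/inter loop ratios and Fisher tests.
- **Functional:** coverage-weighted bedGraph aggregation and median
  signal enrichment per sub-compartment, interval (enhancer-type)
  enrichment, and intra- vs inter-compartment Spearman correlation
  profiles of gene expression over distance.
- **Synthetic data:** a planted-partition simulator emitting every input
  format (contacts, chrom.sizes, BEDPE loops, bedGraph signal, expression
  tables) with known ground truth, so each stage can be scored.

## Worked example

```r
library(subHiC)

cfg <- simConfig(nChroms = 4, binsPerChrom = 15, K = 3,
                 proportions = rep(1/3, 3), seed = 7)
sim <- simulateHiC(cfg)
sim$graph
#> ContactGraph: 60 bins, 1225 inter-chromosomal edges, total weight 1.075e+04

emb <- trainEmbedding(sim$graph,
    trainingConfig(dim = 16, samples = 0.3, seed = 7))   # 0.3M edge draws
asg <- kmeansCluster(emb, k = 3, binTable = sim$binTable, seed = 7)
asg
#> SubCompartmentAssignment: 60 bins, k = 3 (0 unassigned)
#> C1 C2 C3
#> 18 22 20

evaluateAssignment(emb, asg, sim$graph)
#> mean silhouette 0.2659 | Davies-Bouldin 1.4759
#>   label closeness betweenness clustCoef
#> 1    C1    0.8275       1.778    0.7151
#> 2    C2    0.8178       2.364    0.6964
#> 3    C3    0.8148       2.200    0.6894

rt <- intraInterRatio(simulateLoops(sim$truth, cfg), asg)
sprintf("intra/inter loop ratio: %.2f (%d intra, %d inter)",
        rt$ratio, rt$nIntra, rt$nInter)
#> "intra/inter loop ratio: 4.04 (1603 intra, 397 inter)"

mclust::adjustedRandIndex(compartmentLabels(asg),
                          compartmentLabels(sim$truth))
#> [1] 1
```

The simulated loops were drawn with 80 % of loops joining two bins of the
same planted sub-compartment; the recovered annotation concentrates them
accordingly (ratio ≈ 4), and the clustering matches the planted partition
exactly (ARI = 1).

A command-line front end wrapping the same functions ships in
`inst/scripts/subhic`:

```sh
subhic simulate --out sim --seed 3
subhic pipeline --contacts sim/contacts.tsv --chrom-sizes sim/genome.sizes \
                --k 5 --dim 32 --samples 1 --seed 3 --out run
subhic chiapet  --loops sim/loops.bedpe --labels run/subcompartments.bed \
                --chrom-sizes sim/genome.sizes --out chia
```

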