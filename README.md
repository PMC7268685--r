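# phylocong

Congruence diagnostics for phylogenomic supermatrices.

Concatenated multi-gene matrices resolve deep phylogenies — the neuropterid
insect orders are a classic case — but three classes of artifact can
masquerade as phylogenetic signal: lineage-specific compositional
heterogeneity (violations of the stationarity/reversibility/homogeneity
assumptions of standard substitution models), non-random taxon-by-partition
data coverage, and genuine gene-tree discordance hidden by concatenation.
`phylocong` implements the diagnostic layer a phylogenomic study runs
around its trees, for analysts who want every number in that layer
recomputable and testable:

* **Supermatrix QC** — Bowker's matched-pairs test of symmetry per taxon
  pair, `B = Σ_{a<b} (n_ab − n_ba)² / (n_ab + n_ba)` on the divergence
  count table, with the median pairwise *p* as the matrix-level score;
  relative composition frequency variation per partition,
  `RCFV = Σ_s Σ_j |A_sj − Ā_s| / n`, with masking at the inclusive 0.1
  threshold; completeness scores `C_a` (overall, per taxon, pairwise); and
  the decisive-subset filter (data for all taxa, < 30% ambiguous sites,
  ≥ 500 sites).
* **Four-cluster likelihood mapping (FcLM)** — for four predefined taxon
  groups, every sampled quartet is evaluated under the three unrooted
  topologies (five branch lengths optimized by a shared C++ pruning
  kernel), the softmax weights `p_i = exp(l_i) / Σ exp(l_j)` are mapped to
  the seven regions of the 2-simplex, and hypotheses are summarised by
  corner percentages.
* **Signal-destroying permutations** — column-wise, row-wise and mask-only
  schemes that each preserve one confounder (site-rate profile, per-taxon
  composition, coverage pattern) and destroy the rest, so support that
  survives permutation can be attributed to its non-phylogenetic source.
* **Gene-tree quartet support** — the `(q1, q2, q3)` frequencies of the
  three quartet arrangements around every internal edge of a species tree,
  scored against a set of gene trees (the pie-chart annotation of
  summary-coalescent trees; scoring only, no tree search).
* **Ancestral characters** — Sankoff parsimony with per-branch apomorphy
  lists, Mk maximum likelihood (ER/SYM/ARD, AIC/AICc model selection),
  exact marginal ancestral probabilities, and stochastic character mapping
  (10,000 endpoint-conditioned histories by default).
* **Synthetic data** — seeded generators for every input class, with the
  structures the diagnostics detect (compositional shifts, occupancy
  masks, gamma rates, NNI gene-tree discordance, Mk characters), so the
  whole pipeline is testable offline.

## Worked example

The `analysis/` scripts run the whole workflow on a simulated 20-taxon
data set (2,400 nucleotide sites in 3 partitions, a compositional shift on
three lineages, three taxa lacking one partition, 100 gene trees at 20%
NNI discordance, 20 three-state characters):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_supermatrix_qc.R
Rscript analysis/03_likelihood_mapping.R
Rscript analysis/04_permutation_tests.R
Rscript analysis/05_gene_tree_support.R
Rscript analysis/06_ancestral_characters.R
```

Stage 2 prints the QC summary:

```
Bowker: 190 pairs, median p = 0.37, 3.7% rejected at alpha = 0.05
Completeness C_a = 0.9274 (per-taxon 0.682-0.974)
-> 0 partition(s) masked; 2400 of 2400 sites retained
Decisive subset: p1, p2 of 3 partitions survive
```

— no compositional masking is triggered (the simulated shift sits on three
short terminal branches), and the decisive filter correctly drops `p3`, the
partition three taxa lack. Stages 3–4 show the likelihood-mapping
signature of true signal versus its permutation null:

```
corners C1/C2/C3: 99.50% / 0.00% / 0.00%      (original data)
columnwise corners  16.0 /  18.5 /  37.0 %  centre  6.5 %
rowwise    corners   2.5 /   7.5 /   5.5 %  centre 79.0 %
maskonly   corners   7.5 /  10.5 /   6.5 %  centre 65.5 %
```

99.5% of quartets land in the corner of the generating topology; after the
column-wise permutation no corner dominates and the centre (star-like)
region fills — residual corner occupancy on permuted data reflects noise
and the preserved confounder, not phylogeny. Stage 5 annotates each of the
17 internal edges with quartet support (`q1` mean 0.991 at 20% gene-tree
discordance), and stage 6 reconstructs the characters:

```
Best by AIC: ER; by AICc: ER
SCM (10000 histories): E[transitions] = 9.63, max |SCM - exact marginal| = 0.0071
Root state posterior (SCM):  a 0.2525  b 0.5651  c 0.1824
```

`run_pipeline()` wires the same stages into one call with a YAML-able
configuration and writes a checksum manifest; reruns with the same master
seed are byte-identical.

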