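---
title: "Methods: phylogenomic congruence diagnostics in phylocong"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenomic congruence diagnostics in phylocong}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phylocong` implements the diagnostic layer of a phylogenomic study: the
battery of checks a careful analyst runs around a supermatrix phylogeny to
decide whether its signal is trustworthy. This vignette explains the models
and procedures, the tunable parameters with their defaults, the numerical
choices, what the synthetic-data generator does and does not emulate, and
the known limitations. It states no empirical result beyond what the
package's test suite and `scripts/acceptance.R` recompute.

## The problem

Concatenated multi-gene ("supermatrix") phylogenies of groups such as the
neuropterid insect orders combine hundreds of protein-domain-based
partitions into matrices of 10^5–10^6 aligned sites. Three classes of
artifacts can then masquerade as phylogenetic signal:

* **Compositional heterogeneity.** Standard substitution models assume
  stationarity, reversibility and homogeneity (SRH). Lineage-specific shifts
  in amino-acid or base composition violate these assumptions and can draw
  unrelated, compositionally similar taxa together.
* **Non-random data coverage.** Taxon-by-partition occupancy is never
  random; shared missingness patterns can create apparent signal.
* **Gene-tree discordance.** The species tree and individual gene trees can
  genuinely disagree, and concatenation hides that disagreement.

The package provides one tool per artifact class — matched-pairs symmetry
tests and composition scores with masking rules; quartet likelihood mapping
re-run on permuted matrices that destroy true signal but retain a chosen
confounder; per-edge quartet support of a species tree against gene trees —
plus ancestral-state machinery for interpreting a finished phylogeny, and a
simulation layer so every stage can be exercised and calibrated without
external data.

## Supermatrix QC

### Bowker's matched-pairs test of symmetry

For two sequences restricted to their mutually non-missing columns
(pairwise deletion), build the divergence count table $n_{ab}$ (state $a$ in
taxon $i$, state $b$ in taxon $j$). The statistic

$$B \;=\; \sum_{a<b,\; n_{ab}+n_{ba}>0} \frac{(n_{ab}-n_{ba})^2}{n_{ab}+n_{ba}}$$

is referred to the upper tail of $\chi^2_{df}$ with $df$ the number of
informative cell pairs. Under SRH-compliant evolution the divergence process
is symmetric and $B$ is calibrated; composition shifts inflate it. Choices:

* $df = 0$ (e.g. identical sequences) returns $p = 1$: no evidence of
  asymmetry, keeping the median defined for near-identical taxa.
* Zero comparable columns is reported as *missing*, not $p = 1$, and such
  pairs are excluded from the matrix-level median (and counted).
* IUPAC partial ambiguities are treated as missing by default
  (configurable), since a partially ambiguous observation cannot be placed
  in a single divergence cell.

The matrix-level summary is the median pairwise $p$, the per-supermatrix
scalar used to compare data treatments. Internally the statistic is also
cross-checked in the test suite against the McNemar–Bowker test in base R
on dense tables; sparse tables (zero cell pairs) are where the dedicated
implementation differs by design.

### RCFV and masking

Relative composition frequency variation for a partition with $n$ taxa that
have data there:

$$\mathrm{RCFV} \;=\; \frac{1}{n}\sum_{s}\sum_{j} \lvert A_{sj} - \bar A_s \rvert,$$

where $A_{sj}$ is the frequency of state $s$ among taxon $j$'s observed
characters in that partition and $\bar A_s$ the across-taxa mean.
Per-taxon frequencies are computed over observed characters only, so
missingness is not conflated with composition, and taxa without data are
excluded from $n$. Partitions with $\mathrm{RCFV} \ge 0.1$ (inclusive
bound) are masked and the scheme re-indexed.

**Small-sample caveat.** RCFV is not sample-size corrected: under a
perfectly homogeneous process its expectation scales like
$\sum_s \sqrt{2 p_s(1-p_s)/(\pi L)}$ for partition length $L$. For 20
amino-acid states this baseline exceeds the 0.1 threshold for partitions
shorter than roughly 1,200 sites; the threshold is meaningful for the long
meta-partitions it was designed for, but over-masks short desk-scale
partitions. For this reason the bundled demo pipeline simulates nucleotide
partitions (baseline $\approx 1.4/\sqrt{L}$), and engineered fixtures use
homogeneous blocks of 500+ sites.

### Completeness and decisiveness

$C_a$ is the proportion of non-ambiguous cells overall, with per-taxon and
pairwise (shared unambiguous columns) variants. The decisive-subset filter
keeps partitions where (a) every taxon has at least one observed character,
(b) the ambiguous-cell fraction is *strictly* below 0.30, and (c) length is
*at least* 500 sites — strictness follows the wording of the protocol the
defaults encode ("less than 30%", "at least 500").

## The likelihood engine

All likelihood computations (quartet mapping and Mk characters) share one
Felsenstein pruning kernel (C++): postorder partial likelihoods over unique
site patterns, per-node rescaling for underflow, missing states as all-ones
partials, root weighted by the model's equilibrium/prior frequencies, and
discrete-gamma rate mixing in log-space.

* Reversible models are diagonalised once through the symmetric similarity
  $\Pi^{1/2} Q \,\Pi^{-1/2}$, so $P(t)$ is assembled from cached
  eigenvectors inside the kernel — stable and fast in optimizer loops.
  Non-symmetric Mk generators (ARD) fall back to a dense matrix
  exponential.
* Rates are normalised to one expected substitution per unit branch length
  for sequence models; Mk generators are deliberately *not* normalised (the
  rate parameter carries the scale against chronogram time units).
* Discrete-gamma multipliers are the exact conditional means of the
  equal-probability segments of $\mathrm{Gamma}(\alpha,\alpha)$ (four
  categories by default).
* Branch lengths live in $[10^{-8}, 10]$ and are optimized in log-space,
  avoiding boundary pathologies.
* Default amino-acid exchangeabilities are uniform ("poisson") with
  empirical frequencies (pseudocount 1 per state, so tiny quartet
  sub-alignments never hit zero frequencies); empirical matrices can be
  loaded from standard PAML `.dat` files with `read_paml_matrix()`.

The kernel is verified in the test suite against brute-force enumeration of
all internal-state assignments on small trees ($|\Delta| < 10^{-6}$) and
against root-placement invariance for reversible models.

## Four-cluster likelihood mapping

For a hypothesis stated as four disjoint taxon groups, quartets are drawn
one taxon per group — the full Cartesian product when it fits the cap
(default 20,000), otherwise a seeded uniform subsample. Per quartet:

1. Restrict to columns where all four taxa are observed (per-quartet
   complete deletion); skip below 30 usable sites.
2. For each of the three unrooted topologies, maximize the likelihood over
   the five branch lengths (bounded quasi-Newton in log-space, three seeded
   random restarts, so occasional multimodality is caught).
3. Support weights are the softmax of the three optimized log-likelihoods —
   invariant to adding a constant to all three, and exchangeable under group
   relabeling.

```{r}
grp <- groups_from_split(tree, aln)
res <- run_hypothesis(aln, grp, cap = 200, seed = 1)
res$region_pct
```

The weight vector is mapped to one of seven regions of the 2-simplex by a
**nearest-prototype rule**: corners $(1,0,0),(0,1,0),(0,0,1)$, edge
midpoints, and the barycentre, with ties broken in a fixed order. This is a
convex, easily testable approximation of the classical likelihood-mapping
figure; the exact historical region boundaries differ slightly, and the rule
is deliberately isolated behind `assign_region()` so an alternative geometry
is a one-function change. Headline "% of quartets supporting topology $i$"
counts corners only.

One coherent model scores all quartets of a hypothesis: uniform
exchangeabilities, alignment-wide empirical frequencies, and a gamma shape
estimated once on a 50-quartet subsample then fixed. The shape estimate
profiles $\alpha$ with topology and branch lengths held at their
$\alpha = 1$ optima — a deliberate approximation; its only role is to give
all quartets a shared, plausible rate-heterogeneity model.

### Permutations

Three schemes destroy phylogenetic signal while preserving a chosen
confounder, all operating within partitions and leaving shape, taxon order,
partition scheme and missing-cell coordinates bit-identical:

* `scheme_columnwise()` permutes each column's observed residues among the
  taxa covered in that column: preserves the missing-data mask and each
  column's state multiset (hence the site-rate profile); destroys tree
  signal and lineage-specific composition.
* `scheme_rowwise()` permutes each taxon's observed residues across its own
  covered sites: preserves per-taxon per-partition composition (the
  SRH-violation structure symmetry tests react to); destroys shared site
  patterns.
* `scheme_mask_only()` redraws every observed cell i.i.d. from the
  partition's pooled frequencies: preserves only the coverage pattern.

Support that survives a permutation cannot be phylogenetic; comparing the
three schemes attributes it to composition or coverage. The published
permutation protocol this mirrors is defined in supplementary material that
is not redistributed here, so the schemes are specified by their
preserve/destroy contracts (which the tests verify exactly) rather than by
provenance; the column-wise scheme corresponds to the "signal eliminated"
permutation.

### What corner percentages mean at desk scale

With $\sim$10^6 permuted sites, random log-likelihood differences between
topologies are large, weights are near-degenerate, and essentially every
quartet lands in some corner — about a third in each. At the few-hundred-site
scale of the bundled simulations the same differences are only a few
log-units, so a noticeable minority of permuted quartets falls into edge and
centre regions (the centre occupancy visibly increases, which is itself the
diagnostic signature). Corner percentages on permuted desk-scale data are
therefore centred near $\sim$24–28% rather than 33.3%, with correlated
sampling noise across quartets that share taxa. An expectation band of
33.3 ± 10 points per corner — natural at full scale — is marginal at 300
sites, and one corner can fall below it without indicating any topology
bias; the test suite documents this with a uniformity check on fully i.i.d.
quartets.

## Gene-tree quartet support

For each internal edge of the binary species tree, the four incident
subtrees define a quadripartition $A|B|C|D$. Up to 1,000 quartets (one leaf
per part; exhaustive when fewer) are classified in every gene tree by the
four-point condition on topological distances: the pairing with the strictly
smallest distance sum is the induced arrangement, ties are unresolved
(polytomies), and gene trees missing any of the four leaves count as
missing. $q_1, q_2, q_3$ are the frequencies of the three arrangements
among resolved observations — the pie-chart annotation of summary-coalescent
species trees. This is a scoring re-implementation only: there is no
species-tree search, and the sampled per-edge tally is not claimed to equal
a weighted all-quartet normalization, only to estimate the same
$(q_1,q_2,q_3)$ semantics. Unresolved quartets are excluded from the
denominator, with raw counts reported alongside.

## Ancestral characters

### Sankoff parsimony

Generalised parsimony under an arbitrary cost matrix (unit by default):
bottom-up cost vectors, then an outside pass so each node's set contains
exactly the states attained in at least one most-parsimonious
reconstruction. A branch carries an *unambiguous* change only when both
endpoint sets are singletons and differ — every reconstruction then implies
that same change — which is what the per-branch apomorphy list reports.
Equality with Fitch counts on binary trees is a test-suite invariant.

### Mk maximum likelihood and model selection

`mk_fit()` maximizes the pruning likelihood over the rate parameters of an
ER (1), SYM ($k(k-1)/2$) or ARD ($k(k-1)$) generator in log-space, with a
parsimony-informed starting rate (changes per unit total branch length).
The root prior defaults to uniform — the common, testable default; the
protocol this follows does not state its prior — and is configurable.
`mk_model_select()` warm-starts SYM from the ER optimum and ARD from SYM,
which guarantees the nested log-likelihood ordering, and reports AIC and
AICc (sample size = number of characters; both are emitted since the
historical choice between them is not documented). An all-tips-equal
character has a likelihood monotone in the rate; the MLE then sits at the
lower bound and is flagged rather than hidden.

### Stochastic character mapping

`scm_sample()` draws full histories conditional on the tips: node states
jointly (root from its posterior, then pre-order conditional sampling given
the inside partial likelihoods), then each branch's substitution path
conditioned on its endpoints. Path sampling is rejection-first — forward
simulation until the endpoint matches, up to 1,000 attempts — with a
uniformization fallback (jump count drawn from its endpoint-conditioned
distribution, states by a discrete bridge), so the sampler is exact with a
bounded worst case; fallback use is counted and reported. Default 10,000
histories, matching the protocol the package follows. Summaries: node-state
frequencies (whose agreement with the exact marginals from
`marginal_ancestral()` within Monte-Carlo error is an acceptance check),
expected transition counts per ordered state pair (per branch and total),
and expected dwell times.

## The synthetic-data generator

The generator produces every input class the pipeline consumes, with the
statistical structure the diagnostics are designed to detect. All
randomness derives from a master seed through named substreams
(`substream_seed()`), so stages are independently reproducible.

* **Trees**: Yule topologies rescaled to a target height (1.0 by default —
  a realistic root-to-tip substitution load for deep-phylogenomic data, and
  saturated enough that short loci carry limited signal, as real data do).
  `strengthen_split()` pins the length of one internal edge (default
  0.3 substitutions/site) to create a split with known, strong signal for
  recovery experiments.
* **Alignments**: sites i.i.d. given a discrete-gamma category
  ($\alpha = 1$, four categories by default); compositional shifts swap the
  transition matrices on designated terminal branches for those of a model
  with perturbed equilibrium frequencies — the simplest SRH violation a
  symmetry test should detect (covarion-style violations are out of scope);
  occupancy masks overwrite whole taxon-by-partition blocks (plus optional
  per-site dropout) with the missing symbol, mimicking transcriptome-style
  coverage.
* **Gene trees**: the species tree with probability $1-\varepsilon$, else a
  random NNI neighbour ($\varepsilon = 0.2$ in the demo). This exercises
  quartet scoring without claiming coalescent realism; a multispecies
  coalescent generator is a documented extension point.
* **Characters**: CTMC draws from the root prior down the tree under a
  supplied Mk generator (demo: 3 states, ER, rate 0.5 per unit height —
  a handful of expected changes per character).

What the generator does **not** emulate: alignment and masking artifacts,
orthology errors, within-column covariation, indel processes, clocklike
rate variation among lineages. Passing tests on generated data therefore
demonstrate the correctness and calibration of the *diagnostics*, not the
behaviour of real transcriptomic supermatrices.

## Problem sizes and defaults

The bundled analyses and checks run at deliberately desk-scale sizes chosen
to exercise every code path: 20-taxon trees with 300–2,400-site alignments,
200-quartet likelihood-mapping runs, 540 null pairs for symmetry-test
calibration, 10,000 mapping histories, and a 100-taxon/200-character rate
recovery. The statistically delicate quantities (type-I rate bands,
Monte-Carlo error bounds) use sample sizes at which their expected sampling
error is several times smaller than the asserted band, with the exception
discussed above for permuted corner percentages.

## Known limitations

* RCFV's small-sample bias (above): compare partitions of similar length,
  or prefer nucleotide alphabets at desk scale.
* The simplex-region geometry is a documented approximation of the
  classical likelihood-mapping figure.
* Quartet drawing treats quartets as exchangeable; overlapping taxa induce
  correlation between quartets, so region percentages have larger-than-
  binomial sampling error for small groups.
* `mk_fit()` shares one generator across characters; characters with
  heterogeneous state spaces are fit per character instead.
* The pipeline's permutation schemes are contract-defined (preserve/destroy
  lists), not byte-level reproductions of any published permutation scripts.
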