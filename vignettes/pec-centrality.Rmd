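---
title: "PeC: co-clustering and co-expression centrality for essential protein prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PeC: co-clustering and co-expression centrality for essential protein prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pecnet)
```

## The model

Essential proteins cluster: they tend to sit inside densely interconnected,
co-expressed complexes rather than acting alone, while many high-degree
nodes of high-throughput interactomes are artifacts or date hubs whose
partners neither interact with one another nor share expression dynamics.
PeC encodes exactly this contrast. For an undirected simple PPI network
$G(V,E)$, each edge gets a topological co-clustering term

$$ECC(u,v) = \frac{|N_u \cap N_v| + 1}{\min\{d_u, d_v\}},$$

the common-neighbor form of the edge clustering coefficient. The $+1$
keeps the measure informative in triangle-poor regions (a pendant edge
scores 1, not 0), and the $\min$-degree denominator makes $ECC \in (0,1]$
with equality when the sparser endpoint's neighborhood nests inside the
other's. The biological term is the sample Pearson correlation $PCC(u,v)$
of the two genes' expression profiles over $s$ samples (the $s-1$
denominator, clipped to $[-1,1]$ against rounding overshoot). Their product
$p_c(u,v) = ECC(u,v)\,PCC(u,v)$ is interpreted as the probability that the
two interacting proteins belong to one cluster, and

$$PeC(v) = \sum_{u \in N_v} p_c(u,v).$$

Assumptions worth keeping in mind: interactions are unweighted and
undirected; expression profiles are comparable across genes after the
correlation's implicit standardization (no further normalization is
applied); and co-complex membership is taken as the relevant proxy for
essentiality. Negative correlations are *not* clamped — an anti-correlated
neighborhood actively lowers the score, and PeC can be negative.

## Handling missing and degenerate data

Real expression compendia never cover the whole interactome. Scoring must
nevertheless cover every network protein, so the package adopts a single
rule: an edge whose endpoint lacks an expression profile, or whose profile
is constant (zero standard deviation, correlation undefined — signalled as
a `pecnet_degenerate_profile` condition by `pcc()`), contributes
$p_c = 0$. A zero term leaves every sum defined without inventing data;
isolated proteins likewise score 0. This is a package choice — the
convention for expression-less proteins is genuinely open — and it is the
conservative one: such proteins fall to the bottom of the ranking rather
than being dropped from it.

## Comparison centralities

Thirteen classical measures share the `ScoreVector` interface so rankings
are directly comparable: degree (DC), shortest-path betweenness (BC) and
per-component closeness (CC) — these three stand on igraph's
implementations, cross-checked in the test suite against independent
brute-force oracles (geodesic counting by matrix powers, Floyd–Warshall
distances) on exhaustively enumerated small graphs; subgraph centrality
(SC) and eigenvector centrality (EC) via dense symmetric
eigendecomposition; Stephenson–Zelen information centrality (IC) per
connected component from $B=(L+J)^{-1}$; bottleneck centrality (BN);
density of maximum neighborhood component (DMNC, exponent 1.7 per its
published default); local average connectivity (LAC); sum of ECC (SoECC,
the pure-topology reduction of PeC); lobby index (LI); LeaderRank (LR);
and normalized $\alpha$-centrality (NC). SoPCC and per-neighborhood
ECC/PCC averages are provided as diagnostics for dissecting *why* a
protein scores low.

Numerical and tie-break choices, where the literature definitions leave
room:

* **Ranking**: descending score, ties broken by ascending protein
  identifier — every ranking is a deterministic permutation of the node
  set.
* **BN**: one BFS shortest-path tree per root, neighbors explored in
  lexicographic identifier order; a node is a bottleneck when its subtree
  (itself included) holds strictly more than $n_c/4$ of the root's
  component. The cited definition leaves the tree choice open;
  lexicographic determinism makes the measure testable, at the price that
  BN — alone among the suite — is not invariant under relabeling when
  BFS ties exist.
* **CC / IC on disconnected graphs**: computed within each component with
  within-component normalization; isolated nodes score 0 (CC, IC) or 1
  (SC, its walk-count floor).
* **DMNC**: the maximum neighborhood component is the largest component of
  the neighborhood subgraph, ties broken by edge count.
* **NC**: solves $c = \alpha A c + e$ directly; default
  $\alpha = 0.9/\lambda_{max}$, strictly inside the Katz convergence
  radius.
* **LR**: degree-normalized walk on the ground-node-augmented graph,
  iterated to a $10^{-10}$ max-change fixed point; total score is
  conserved at $n$.
* **ECC**: computed for all edges in one vectorized pass (common-neighbor
  counts via a sparse matrix product). The edge table is the unit of reuse:
  evaluation layers compute it once per frozen graph instead of caching
  per-edge values inside a mutable structure, which R's copy-on-modify
  semantics would make fragile.
* Scores are doubles throughout; CSV output formats to 6 significant
  digits.

## Evaluation protocol

Proteins are ranked by each measure; the top $k$ are called as candidate
essentials and checked against the annotation. Unknown-status proteins
count as non-essential in these counts — with a three-way annotation the
alternative would inflate precision. The jackknife curve records the
cumulative count of true essentials at every rank. As an area under this
curve the package uses the rectangle rule,

$$AUC = \frac{1}{nE}\sum_{i=1}^{n} c_i,$$

with $c_i$ the cumulative count at rank $i$ and $E$ the number of
essentials: a perfect ranking scores $1-(E-1)/(2n)$, a random one
$(n+1)/(2n)\approx 1/2$. No standard normalization exists for this curve,
so only AUC *orderings* are meaningful across measures, never absolute
values across data sets. Random-assortment baselines are uniform
permutations of the node set, reproducible from a seed.

The overlap report mirrors a top-$k$ contingency analysis between a
reference measure (PeC by default) and each comparison measure:
$|PeC \cap M_i|$, $|M_i - PeC|$, the number of annotated nonessentials in
the difference set, and the percentage of those nonessentials whose
reference score falls below a threshold (default 0.55) — the screen for
false positives that the reference measure would have discarded. The
nonessential count uses the strict `nonessential` status, keeping the
three-way annotation split visible; an empty difference set reports 0.

## The synthetic generator

`generate_fixture()` emulates the features the method relies on, not a
yeast interactome wholesale. Its planted-partition graph wires same-cluster
pairs with probability `p_in = 0.8` and all other non-hub pairs with
`p_out = 0.01`; expression is
$\sqrt{\rho}\,\ell_{c(v)} + \sqrt{1-\rho}\,\varepsilon_v$ with i.i.d.
standard-normal samples, giving expected within-cluster pairwise
correlation exactly `rho_in` (one parameter controls the co-expression
signal); essentiality is Bernoulli, 0.8 inside clusters versus 0.1
outside. Decoy hubs are reserved nodes excluded from background wiring,
attached to `hub_degree = 15` sampled background proteins, with any edges
among a hub's neighbors removed — reproducing the star-like, uncorrelated
neighborhoods of degree-based false positives. The defaults (500 proteins,
ten clusters of twelve, 36 samples, seed 42) are the package's reference
study conditions; 36 samples matches the expression compendium size the
method was designed around, and the remaining values are what we consider
realistic for complex-enriched subnetworks at desk scale.

What the generator does *not* model: the heavy-tailed degree distribution
of real interactomes beyond the planted hubs, false-negative edges,
correlated noise across samples (time-course autocorrelation), and
partial expression coverage. Passing tests on these fixtures therefore
demonstrate that the implementation realizes the model's mechanism —
cluster members outrank equal-degree decoys, rankings beat random — not
that PeC attains any particular precision on a real organism.
`generate_decoy_contrast()` isolates the mechanism in its purest form: a
degree-$k$ star with noise profiles against a $(k+1)$-clique sharing one
profile (every clique edge has $ECC = PCC = 1$, so the clique member's
PeC equals $k$ exactly).

## Reproducibility

All generators and baselines take explicit integer seeds and the file
formats are deterministic (canonical lexicographic edge lists, sorted
score CSVs), so `simulate → score → evaluate` reruns are byte-identical —
this is asserted in the test suite. The command-line wrapper `exec/pec`
exposes `simulate`, `score` and `evaluate`; a comparison run is `score`
with several `--measures`, which writes the combined wide CSV that
`evaluate` consumes, including externally computed score columns appended
by the user.

## Limitations

PeC inherits the quality of both inputs: with few expression samples the
correlation estimates are noisy, and with fragmented networks ECC loses
resolution. The integration is a bare product — no weighting between the
topological and biological terms is exposed, matching the original design.
Statistical significance of AUC differences is out of scope, as are
directed or weighted interaction semantics and any identifier mapping
between expression and network namespaces beyond exact string equality.
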