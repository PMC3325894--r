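# pecnet

Essential proteins — those whose deletion is lethal — are enriched among
highly connected nodes of protein–protein interaction (PPI) networks, but
degree alone is a noisy predictor: high-throughput interactomes carry many
false-positive edges, and some hubs sit at the center of star-like
neighborhoods that do not correspond to any real protein complex. `pecnet`
implements **PeC**, a centrality that integrates network topology with gene
expression, for computational biologists who rank candidate essential
proteins before committing to knockout experiments.

## The measure

For an interaction \(e(u,v)\) the *edge clustering coefficient* uses common
neighbors rather than triangles, so it stays informative in sparse networks:

```
ECC(u,v) = (|N_u ∩ N_v| + 1) / min{d_u, d_v}        ∈ (0, 1]
```

where `N_v` is the neighbor set and `d_v` the degree. The co-expression of
the two genes across `s` samples is the sample Pearson correlation
`PCC(u,v)` (s−1 denominator). Their product

```
pc(u,v) = ECC(u,v) × PCC(u,v)
```

is read as the probability that `u` and `v` occupy the same cluster
(complex), judged jointly from topology and expression, and a protein's
score is the sum over its interaction partners:

```
PeC(v) = Σ_{u ∈ N_v} pc(u,v)
```

A protein scores high only when it is *both* densely interconnected *and*
co-expressed with its neighborhood; hubs with mutually unconnected or
uncorrelated partners — classic false positives of degree-based ranking —
score near zero. Negative correlations propagate, so PeC can be negative.

The package also provides thirteen comparison centralities (DC, BC, CC, SC,
EC, IC, BN, DMNC, LAC, SoECC, LI, LR, NC), the diagnostic aggregates SoPCC
and per-neighborhood ECC/PCC averages, an evaluation layer (top-k essential
counts, jackknife cumulative-essential curves with AUC and random
baselines, overlap/difference reports between measures), and a synthetic
interactome generator with planted co-expressed clusters and decoy hubs.
See `vignette("pec-centrality")` for the model, parameter choices and
limitations.

## Worked example

```r
library(pecnet)

fx <- generate_fixture(synthetic_spec())   # 500 proteins, seed 42
pec <- pec_scores(fx$network, fx$expression)
ranked <- rank_proteins(pec)
head(ranked, 5)
#>   protein    score
#> 1   P0008 7.616653
#> 2   P0040 6.966983
#> 3   P0007 6.468009
#> 4   P0010 6.379541
#> 5   P0095 6.303761

top_k_essential(ranked, fx$annotation, 100)
#> [1] 87

auc_pec <- jackknife_auc(ranked, fx$annotation)
auc_dc  <- jackknife_auc(rank_proteins(dc_scores(fx$network)), fx$annotation)
rand <- random_assortments(fx$network, fx$annotation, count = 10, seed = 42)
sprintf("AUC  PeC %.3f | DC %.3f | random %.3f",
        auc_pec, auc_dc, mean(sapply(rand, `[[`, "auc")))
#> [1] "AUC  PeC 0.728 | DC 0.721 | random 0.502"
```

The top of the PeC ranking is dominated by members of the planted
co-expressed clusters (87 of the top 100 are truly essential here), and the
jackknife AUC — the normalized area under the cumulative-essential curve —
beats both plain degree and random ordering. The hub/clique contrast shows
*why*:

```r
dd <- generate_decoy_contrast(k = 10, s = 36, seed = 1)
p <- pec_scores(dd$network, dd$expression)
sprintf("decoy hub PeC %.3f vs clique member PeC %.3f (both degree 10)",
        p[[dd$hub]], p[[dd$clique_member]])
#> [1] "decoy hub PeC -0.895 vs clique member PeC 10.000 (both degree 10)"
```

Degree ties the star hub with the clique member; PeC separates them by two
orders of magnitude.

## Command line

`exec/pec` wraps the same functions for shell pipelines:

```sh
pec simulate --out fx --seed 42
pec score    --network fx/network.tsv --nodes fx/nodes.txt \
             --expression fx/expression.tsv --measures PeC,DC,SoECC --out scores
pec evaluate --scores scores/scores.csv --annotation fx/annotation.tsv \
             --k 100,200,300 --out eval
```

Real data plug in the same way: an edge-list or SIF network (self and
duplicate interactions are filtered on load), an expression TSV (proteins ×
samples), and a `protein TAB essential|nonessential|unknown` annotation,
e.g. merged from several knockout databases with `merge_annotations()`.

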