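# oiip — ontology-weighted protein complex detection

Protein complexes leave a double signature: their members are densely
interconnected in protein–protein interaction (PPI) networks *and* they
share biological function. High-throughput PPI data, however, are noisy —
many recorded interactions are false positives — so clustering the raw
graph is unreliable. `oiip` is an R implementation of the OIIP approach
for biologists and method developers working on complex prediction: it
converts a PPI network into a weighted graph using Gene Ontology (GO)
annotations plus local topology, detects complexes by seeded greedy
expansion on the weighted graph, and scores predictions against a
benchmark catalogue.

## The method in brief

Every edge `[u, v]` is weighted by

```
w(u, v) = S_sem(u, v) + topo(u, v)
```

where `topo(u, v)` is the number of neighbours shared by `u` and `v`, and
`S_sem` is a GO semantic similarity driven by the annotation size `m` of
the most specific term annotating both proteins (after transitive
propagation of annotations to ancestors):

```
S_sem(x, y) = 1 − ln(m) / ln(S_max)     (clamped to [0, 1])
```

with `S_max` the largest annotation size in the ontology. Vertices are
ranked by summed incident weight into a seed queue `Sq`. A cluster `K`
grows from the top seed by repeatedly admitting the external neighbour `v`
with the highest interaction probability `E_vK = e_vK / w_K` (edge weight
into `K` over internal weight of `K`), provided `E_vK ≥ T_in` and the
induced diameter of `K + v` stays ≤ `d` (defaults: `T_in = 0.4`, `d = 2`).
Predictions are evaluated by neighbourhood-affinity matching
(`NA(p, b) = |Vp ∩ Vb|² / (|Vp|·|Vb|)`, threshold ω = 0.25) giving
precision/recall/F, by the overlap-matrix scores Sn/PPV/Acc, and by
hypergeometric functional homogeneity.

## Worked example

Everything is runnable offline: the package ships a seeded generator of
synthetic toy inputs (OBO ontology, GAF annotations, edge list, benchmark)
with planted ground-truth complexes.

```r
library(oiip)

bundle <- make_planted_network(
  fixture_spec(n_complexes = 5, complex_size_range = c(4, 6),
               p_in = 1, p_out = 0, annotation_fidelity = 1, rng_seed = 1))

dag <- parse_obo(bundle$obo)
idx <- propagate_annotations(parse_gaf(bundle$gaf, dag), dag)
net <- assign_edge_weights(read_edge_list(bundle$edges), idx)
net
#> Weighted PPI network: 23 vertices, 43 edges
#>   total edge weight: 147.337

cs <- oiip_cluster(net)
cs
#> OIIP result: 5 clusters (t_in = 0.4, d = 2, min_size = 2)
#>   sizes: min 4, median 4, max 6

evaluate_predictions(cs, bundle$truth)
#> Complex prediction report (omega = 0.25)
#>   predicted: 5 (matched 5)   benchmark: 5 (matched 5)
#>   precision 1.0000  recall 1.0000  F 1.0000
#>   Sn 1.0000  PPV 1.0000  Acc 1.0000
```

Five disjoint planted cliques, perfectly annotated, are recovered exactly:
all six scores are 1. On noisy fixtures (`p_in < 1`, `p_out > 0`, imperfect
annotation) the scores degrade gracefully; `oiip_tin_sweep()` shows how
raising `T_in` shrinks clusters and trades recall for precision.

A command-line wrapper (`inst/cli/oiip.R`) exposes the same pipeline as
subcommands `weight | cluster | evaluate | enrich | simulate`; see
`?oiip_cli`.

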