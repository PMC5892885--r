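# ognet — essential-protein prediction from networks, co-expression, and orthology

Essential proteins are those a cell cannot survive or reproduce without.
Because knockout screens are slow and expensive, a standard computational
shortcut ranks proteins in the protein–protein interaction (PPI) network by
a centrality measure and treats the top of the ranking as essential
candidates (the centrality–lethality rule). Pure topology is noisy, though:
interactomes are incomplete, and essentiality also reflects biology the
graph does not carry.

`ognet` is an R package for researchers in network/systems biology that
implements the **OGN** centrality, an evidence blend over three data
sources. For a protein *u* in an undirected PPI network *G(V, E)*:

```
OGN(u) = α · OS(u) + (1 − α) · TPN(u) / max_x TPN(x),          α ∈ [0, 1]

TPN(u) = Σ_{v ∈ N_u} PCC(u, v) · Co(v)
Co(v)  = 2 · #{edges among neighbours of v} / (k_v (k_v − 1))
```

where `PCC(u, v)` is the Pearson correlation of the two genes' expression
profiles, `Co(v)` the local clustering coefficient of neighbour *v*, and
`OS(u)` the fraction of reference organisms containing an ortholog of *u*,
max-normalized over the universe. A protein scores highly when it sits in a
cohesive, co-expressed neighbourhood (complex/party-hub signal, also
crediting date hubs via the *neighbours'* cliquishness) and is conserved
across genomes. A majority-voting **ensemble** over an α-grid
(`ogn_ensemble()`) removes the need to pick α for a new organism: a protein
is selected only if it appears in the top-*n* of more than *T* of the *M*
rankings.

The package also provides the five standard topology-only baselines
(degree, betweenness, closeness, eigenvector, subgraph centrality), the
top-*n* / Jackknife / precision–recall evaluation protocol, readers for
plain and BioGRID TAB edge lists, expression, orthology, and label files,
a seeded synthetic benchmark generator with planted essential modules, and
an `ognet` command-line tool (`exec/ognet`) with `centrality`, `score`,
`ensemble`, `evaluate`, and `simulate` subcommands.

## Worked example

```r
library(ognet)

ds  <- generate_dataset(synthetic_spec(seed = 1))   # planted benchmark
#> Synthetic benchmark dataset: 500 proteins, 1825 interactions, 100 essential (seed 1)
u   <- build_universe(ds$network, ds$expression, ds$orthology)
fit <- ogn(u, alpha = 0.3)
fit
#> OGN essentiality score fit
#>   alpha = 0.3 (PCC policy: raw)
#>   500 proteins scored; top-ranked: P0054, P0057, P0060, P0059, P0053

predict(fit, n = 5)                       # top-ranked candidates
#> [1] "P0054" "P0057" "P0060" "P0059" "P0053"
count_true(predict(fit, 50), ds$labels)   # planted essentials in the top 50
#> [1] 37

ens <- ogn_ensemble(u, n = 50, threshold = 5)
ens
#> OGN majority-voting ensemble
#>   M = 11 alpha values, top n = 50, threshold T = 5 (ES > T)
#>   candidate pool |X| = 91; selected candidates = 50
count_true(ens$candidates, ds$labels)
#> [1] 40

top_n_report(list(OGN = coef(fit), DC = degree_centrality(u$graph)),
             ds$labels, n_values = c(50, 100))
#>   method   n true_positives precision
#> 1    OGN  50             37      0.74
#> 2    OGN 100             72      0.72
#> 3     DC  50             35      0.70
#> 4     DC 100             72      0.72
```

The numbers mean: of the 50 (resp. 100) top-ranked proteins, 37 (72) are
truly essential in the planted ground truth, and the ensemble's 50
candidates contain 40 — the blend and the vote both beat plain degree
centrality at the tight budget. `jackknife()`, `precision_recall()`, and
`plot(fit, labels = ...)` give the full curves.

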