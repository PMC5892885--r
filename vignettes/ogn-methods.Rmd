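---
title: "Scoring protein essentiality with OGN: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring protein essentiality with OGN: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ognet)
```

## The problem and the model

Essential proteins are those an organism cannot survive or reproduce
without. Knockout screens that identify them are slow and costly, so a long
line of computational work ranks proteins by network centrality in the
protein–protein interaction (PPI) network, exploiting the
centrality–lethality rule: highly connected proteins are more often
essential. Topology alone, however, is noisy — interactomes are incomplete,
and essentiality also reflects biology that the graph does not carry.

`ognet` implements the OGN centrality, which blends three data sources. For
a protein $u$ in an undirected PPI network $G(V, E)$:

$$\mathrm{OGN}(u) \;=\; \alpha\,\mathrm{OS}(u) \;+\;
  (1-\alpha)\,\frac{\mathrm{TPN}(u)}{\max_{x \in V}\mathrm{TPN}(x)},
  \qquad \alpha \in [0, 1],$$

with the topological term

$$\mathrm{TPN}(u) = \sum_{v \in N_u} \mathrm{PCC}(u, v)\,\mathrm{Co}(v),
  \qquad
  \mathrm{Co}(v) = \frac{2\sum_{i \in N_v} w(v,i)}{k_v\,(k_v - 1)},$$

where $N_u$ is the neighbour set of $u$, $k_v$ the degree of $v$,
$w(v,i) = 1$ iff $i$ and a fellow neighbour of $v$ interact, so
$\mathrm{Co}(v)$ is the local clustering coefficient of $v$, and
$\mathrm{PCC}(u,v)$ is the Pearson correlation of the two genes' expression
profiles. $\mathrm{OS}(u)$ is the fraction of reference organisms containing
an ortholog of $u$, max-normalized across the analysis universe so the most
conserved protein scores exactly 1.

The intuition: a protein embedded in a cohesive, co-expressed neighbourhood
(a protein complex, or "party hub") gets a high TPN; summing the
*neighbours'* cliquishness rather than the node's own also credits "date
hubs", whose partners form several separate cliques. Conservation across
many genomes is an independent, long-timescale signal of essentiality. The
weight $\alpha$ trades the two off; neither channel alone is as informative
as the blend.

### Majority-voting ensemble

Because the best $\alpha$ is organism-dependent and unknown for a new
species, `ogn_ensemble()` removes the choice: for a grid
$\alpha_1, \dots, \alpha_M$ (default $0, 0.1, \dots, 1$, $M = 11$) it takes
each ranking's top-$n$ set $X_i$ and scores each protein by
$\mathrm{ES}(u) = \sum_{i=1}^{M} I_i(u)$, the number of top-$n$ sets
containing it. Proteins with $\mathrm{ES}(u) > T$ are the ensemble's
candidates. A protein must therefore rank highly under most blend weights to
be selected, which trades a smaller candidate set for higher precision as
$T$ grows.

The strict comparator ($> T$) follows the verbal description of majority
voting; with $M = 11$ a threshold of $T = 5$ under the strict rule is the
same set as $T \ge 6$ under a non-strict one. The comparator is exposed
(`comparator = "gt"`/`"ge"`) because published ensemble tables can be read
either way, and a warning (not an error) is raised for thresholds below the
majority point $\lceil M/2 \rceil$ — sub-majority thresholds are still
well-defined votes.

## Parameters that matter

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `alpha` | 0.3 | $[0,1]$ | Leans on topology/co-expression while retaining conservation; rankings are empirically stable for $\alpha \in [0.2, 0.6]$, and the ensemble removes the choice entirely. |
| `pcc_policy` | `"raw"` | raw / clamp | The TPN definition places no sign restriction on PCC, so signed correlations are the default; `"clamp_nonnegative"` floors them at 0 for users who read PCC as a co-expression probability. |
| `zero_variance_pcc` | 0 | $[-1,1]$ | A constant expression profile carries no co-expression evidence. |
| `n` (ensemble) | 100 | candidates | The fixed-budget protocol size; evaluation sweeps 100–600. |
| `threshold` | 5 | votes, $\le M$ | See above. |

## Conventions for degenerate inputs

* $k_v \le 1$: $\mathrm{Co}(v) = 0$ (the denominator $k_v(k_v-1)$ vanishes;
  a leaf's neighbourhood cannot be a clique of two).
* Isolated proteins: $\mathrm{TPN} = 0$ (empty sum).
* Constant expression profile: every PCC involving it is
  `zero_variance_pcc` (default 0).
* Protein missing from the orthology table: raw OS $= 0$ (no recorded
  ortholog is zero evidence of conservation); an all-zero table gives all
  proteins OS $= 0$.
* $\max \mathrm{TPN} \le 0$ (possible with raw signed correlations on
  pathological data): the normalization is undefined, so the topological
  term is set to 0 for every protein and a message records the convention.
* Ranking ties are broken by ascending protein identifier, so every ranking
  and every output file is deterministic.

## Numerical choices

Betweenness counts each unordered source–target pair once; closeness uses
the component-local (Wasserman–Faust) form $(n_c - 1)/\sum d$ so
disconnected interactomes are handled; both choices only fix a monotone
variant — all evaluation downstream is rank-based. Eigenvector centrality is
power iteration on $A + I$ (same eigenvectors as $A$; the unit shift makes
the Perron eigenvalue strictly dominant in magnitude, so bipartite networks
— e.g. stars — converge instead of oscillating) from a uniform start, with
tolerance $10^{-10}$ on the max absolute change and a hard cap of 1000
iterations that errors rather than returning an unconverged vector.
Subgraph centrality $(e^A)_{vv}$ is computed from the dense spectral
decomposition, which is exact to rounding and adequate at the network sizes
this package targets. Pairwise PCC is computed from standardized profile
rows, touching only the $|E|$ pairs the TPN sum needs rather than an
$|V|^2$ matrix.

## What the synthetic benchmark emulates — and what it does not

`synthetic_spec()` / `generate_dataset()` produce a seeded benchmark with
planted signal in all three channels:

* **Modules.** Essential proteins are partitioned into complexes of
  `module_size = 10`, wired at `p_within_module = 0.9` over a sparse
  background (`p_background = 0.01`) — cohesive party-hub clusters.
* **Decoys.** `n_decoy_modules = 5` non-essential modules share the exact
  topology and co-expression signature. Real interactomes contain cohesive,
  co-expressed complexes that are *not* essential; the decoys are what
  makes topology alone insufficient.
* **Co-expression.** Module members load on a shared latent factor with
  loading $\sqrt{\rho}$ plus unit idiosyncratic Gaussian noise, giving an
  exact target intra-module pairwise correlation `rho_within = 0.8` — the
  simplest construction with a closed-form target.
* **Conservation.** Ortholog counts are
  $\mathrm{Binomial}(99,\, 0.25 + 0.05\cdot[\text{essential}])$,
  i.e. a modest conservation shift on 99 reference organisms.
* **Date hubs** (optional, `n_date_hubs`): high-degree essentials whose
  partners span modules, with weak staggered correlation to all of them —
  exercising the neighbour-focus of TPN.

The defaults were fixed at design time so that *each single channel is
informative but insufficient*: with them, pure topology ($\alpha = 0$) and
pure conservation ($\alpha = 1$) recover a similar number of planted
essentials in the top 50 (means near 32–35 over 20 seeds) while the blend
at $\alpha = 0.3$ recovers distinctly more (means near 37–40). That is the
qualitative regime reported for real yeast data — both endpoints worst,
an interior $\alpha$ best — and it is what makes the benchmark a meaningful
test of the blend rather than of either channel.

The generator does **not** attempt to match real interactomes in degree
distribution (no scale-free tail), network scale (hundreds of proteins, not
tens of thousands), assay noise structure (no spoke-model bait artefacts,
no false-negative edges correlated with abundance), or expression dynamics
(no cell-cycle periodicity). Passing tests on it therefore demonstrate the
correctness and the qualitative behaviour of the method, not its accuracy
on any real organism.

Problem sizes used by the test suite and the acceptance script — 500
proteins, 100 planted essentials, 36 samples, 20 replicate seeds, top-50
budgets — were chosen as the smallest sizes at which the module structure,
vote counts, and replicate means are stable; oracle cross-checks run on
100 random graphs of up to 15 nodes, where brute-force path enumeration is
exact and instant.

## Design decisions on genuinely open points

* **Universe definition.** The analysis universe is the intersection of the
  network's and the expression matrix's proteins, sorted lexicographically;
  it is *not* restricted to the largest connected component (no such
  restriction is standard, and the component-local centralities handle
  disconnection). Proteins missing orthology entries stay in the universe
  with count 0.
* **Duplicate expression profiles** collapse to the row with maximal mean
  across samples (ties: first in file order) — the conventional
  probe-selection rule for this task.
* **`n_reference`** is an explicit input (directive line or argument), not
  a constant: ortholog databases differ in how many reference genomes they
  index and whether the query organism itself is counted.
* **Edge-list format.** Plain two-column lists cannot represent isolated
  vertices, so `write_network()` records them as `#node <id>` comment
  directives that `read_network()` understands and other tools ignore.
* **BioGRID dialect** accepts physical and genetic interactions by default
  (`physical_only = TRUE` to restrict); rows with `-` placeholder
  systematic names are skipped with a logged count.

## Known limitations

OGN needs all three inputs; with no expression data TPN collapses and with
no orthology data the method degenerates to $\alpha = 0$. The subgraph and
betweenness baselines use dense/exact algorithms suited to networks of up
to a few thousand proteins, not organism-scale interactomes with $10^5$
edges. Evaluation treats essentiality labels as ground truth even though
public annotations disagree between databases; precision against such
labels underestimates true precision when "non-essential" includes
fitness genes.
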