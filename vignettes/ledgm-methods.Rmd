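---
title: "Methods: the local effective distance-integrated gravity model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the local effective distance-integrated gravity model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ledgm)
```

## The problem

Given an undirected, unweighted network — a protein-interaction map, a
contact network, a collaboration graph — which nodes are the most potent
spreaders? Degree counts immediate neighbours only; betweenness and
closeness see global structure but ignore how a spreading process actually
moves; k-shell coreness captures position but collapses many nodes onto few
shells. Gravity-model centralities combine a "mass" for each node with a
"distance" between node pairs, scoring node $i$ by
$\sum_j m_i m_j / d_{ij}^2$, and differ in what they plug in for mass and
distance.

The model this package implements — LEDGM, the *local effective
distance-integrated gravity model* — makes two specific choices:

1. **Distance is effective distance.** A single step from node $i$ to an
   adjacent node $j$ is taken with probability $P_{j|i} = 1/k_i$, and the
   corresponding length is $D_{j|i} = 1 - \log_2 P_{j|i} = 1 + \log_2 k_i$.
   A hub spreads its attention over many neighbours, so each neighbour is
   effectively farther from it. Multi-hop distances are shortest additive
   paths over these directed one-hop lengths; since every length is
   $\ge 1$, Dijkstra's algorithm applies. The measure is asymmetric:
   $D_{j|i} \ne D_{i|j}$ whenever the endpoint degrees differ.

2. **Mass is propagation capability.** Each node's mass fuses degree,
   coreness and clustering:
   $$sp_i = e^{-C_i}\left(\frac{k_i}{k_{max}} + \frac{ks_i}{ks_{max}}\right),$$
   where $C_i$ is the local clustering coefficient
   ($2 n_i / (k_i (k_i - 1))$ with $n_i$ the edges among $i$'s neighbours),
   $k_i$ the degree and $ks_i$ the k-shell index. Tightly clustered
   neighbourhoods are discounted — edges that close triangles around $i$
   reach few new nodes — while degree and core position contribute on
   equal, normalized footing.

The score of node $i$ is the total attraction over its
*effective-influence set* $\varphi_i$:
$$IEDG_i = \sum_{j \in \varphi_i} \frac{sp_i \, sp_j}{D_{j|i}^2},
  \qquad \varphi_i = \{\, j \ne i : d_{j|i} \le R \,\},$$
with $d_{j|i}$ the hop distance and $R$ the truncation radius, set to half
the hop diameter (floored, never below 1). The truncation is what makes
the method *local*: effective distances are computed only for the
$\sum_i |\varphi_i|$ pairs inside the influence sets rather than all
$N(N-1)$ ordered pairs, and `ledgm_unrestricted()` (the "R-LEDGM" variant)
exists precisely to measure what that truncation changes — on the seven-node
example below, nothing for the hub (whose influence set already spans the
network) and a modest downward shift for peripheral nodes, at roughly half
the pair count (22 of 42).

## Worked example

The seven-node network bundled as `figure1_network()` exercises every step
at desk scale:

```{r example}
g <- figure1_network()
round(propagation_capability(g), 4)
influence_sets(g)$sets[["2"]]
direct_effective_length(g, "2", "1")
round(ledgm(g)$scores, 4)
round(ledgm_unrestricted(g)$scores, 4)
```

This fixture is not hand-drawn: `reconstruct_figure1_by_search()`
enumerates all $2^{15}$ graphs on seven labelled nodes in which node 1 is
adjacent to all others, filters by the network's published structural
facts (node 2 has degree 2 with neighbourhood $\{1, 5\}$, $C_2 = 1$,
$C_1 = 1/3$, the 2-shell membership) and by both seven-value score rows,
and exactly one graph survives (up to the swap of the interchangeable
nodes 2 and 3). The search ships as a standing test, so the fixture cannot
silently drift from the constraints that define it. Without the score-row
filter, 125 candidate graphs survive the structural constraints alone —
the score rows are load-bearing.

A note on comparison precision: the reference seven-value score rows carry
four decimals, and inspection shows they are *truncated*, not rounded
(the unrestricted score of node 2 is 0.34425046, printed as 0.3442). Tests
therefore compare the restricted row at $5 \times 10^{-5}$ and the
truncation-affected unrestricted row at one printed ulp ($10^{-4}$).

## Comparator centralities

`node_centrality(g, method)` dispatches the eight measures used in the
ranking comparisons: `dc` (degree), `bc` (betweenness, unnormalized, over
unordered pairs), `cc` (closeness, $(N-1)/\sum_j d_{ij}$), `ks` (k-shell),
`gm` (degree-mass gravity over hop distances $\le R$), `edgm`
(degree-mass gravity over all-pairs effective distances, no truncation),
`ggm` (gravity with mass $e^{-\alpha C_i} k_i$ over hop distances
$\le R$), plus `ledgm` and `rledgm`. With $\alpha = 0$ the GGM collapses
onto the GM exactly — a useful identity that the tests assert on random
graphs. The GGM's $\alpha$ has no canonical value; it is an explicit
parameter defaulting to 1, and is recorded in each result's parameter
record.

## The SI benchmark

Ground truth for spreading power is a discrete-time
susceptible–infected process: at each step every infected node
independently infects each susceptible neighbour with probability
$\beta$; newly infected nodes transmit from the next step; nobody
recovers. A susceptible node with $m$ infected neighbours is infected
with probability $1 - (1 - \beta)^m$, which is how the simulator draws it
(one uniform per susceptible node per step — distributionally identical
to the per-contact trials and vectorizable).

Design choices that the process description leaves open, fixed here once:

* **Updates are synchronous** — the standard network convention, and the
  one consistent with step-indexed spread curves.
* **Influence statistic**: `single_seed_influence()` seeds each node
  alone and reports the mean infected count at a configurable horizon
  (default `steps = 10`) over `runs = 100` repetitions. The benchmark
  experiments use $\beta = 0.2$.
* **RNG discipline**: a master seed spawns one deterministic sub-seed per
  run, so identical seeds give bit-identical curves and *extending* the
  run count never perturbs the earlier runs.

Ranking agreement is measured by Kendall's tau-a,
$\tau = 2 (n_a - n_b) / (N (N - 1))$, by direct pair enumeration. Tied
pairs count as neither concordant nor discordant and no tie correction is
applied, so a heavily tied benchmark (e.g. $\beta = 0$, where every
influence is 1) yields $\tau = 0$ against everything. This is deliberate:
tau-a is the definition the evaluation is specified with; tau-b would
change the numbers.

`kendall_vs_beta_sweep()` assembles the accuracy-versus-$\beta$
comparison; `timing_benchmark()` compares the truncated and unrestricted
models. Wall-clock timings are reported but hardware-dependent; the
deterministic quantity is the pair-count reduction
$\sum_i |\varphi_i|$ vs $N(N-1)$, which the tests assert on an
Erdős–Rényi graph with 2000 nodes and edge probability 0.005.

## Synthetic data

`erdos_renyi_graph(n, p, seed)` draws $G(n, p)$: each of the
$\binom{n}{2}$ pairs is an edge independently with probability $p$. The
scale-study configurations are $n = 100$ at $p = 0.05$, $n = 500$ and
$1000$ at $p = 0.01$, and $n = 2000$ at $p = 0.005$ — densities chosen so
that mean degree stays moderate ($5$–$10$) and an SI epidemic does not
flood the network in two steps, which would erase the differences between
seed rankings. What $G(n, p)$ does *not* emulate: heavy-tailed degree
distributions, community structure, degree assortativity and the high
clustering of real collaboration or communication networks. Tests passing
on these graphs demonstrate correctness of the computations, not that the
method's accuracy advantage carries to any particular real network.

Test-scale choices: property tests run on graphs of 12–50 nodes (where
exhaustive oracles — all-simple-paths enumeration for effective
distances, matrix-power path counts for betweenness, triangle
enumeration for clustering — are feasible), SI checks on 40–100 nodes
with 20–300 repetitions, and the pair-count check on the 2000-node
configuration above.

## Numerical and degenerate-input conventions

* $C_i = 0$ when $k_i \le 1$ (the formula is 0/0 there); isolated nodes
  get k-shell 0.
* Effective-influence membership is $d_{j|i} \le R$: on the worked
  example ($R = 1$), node 2's set is $\{1, 5\}$ at hop distance exactly 1,
  which pins the boundary convention down unambiguously.
* $R = \max(1, \lfloor \mathrm{diameter}/2 \rfloor)$, computed on the
  largest component; an override is exposed (`ledgm(g, radius = ...)`)
  for sensitivity analysis.
* Disconnected pairs have infinite distance and contribute zero
  attraction — never an error. Closeness on a disconnected graph is
  computed within each node's component with that component's size, with
  a warning. Influence sets never cross components.
* All scores are carried at full double precision; rounding happens only
  at presentation (the CLI prints 6 decimals).
* Rankings break score ties by ascending node id, numerically when all
  ids are numeric; every reported ordering is therefore stable and
  reproducible.

## Limitations

* Directed and weighted graphs are out of scope; the model is defined on
  undirected simple graphs.
* The all-pairs variants (`edgm`, `rledgm`) cost a Dijkstra run per node
  over the whole graph and are the known bottleneck at scale — which is
  the point of the truncated model.
* The SI benchmark's horizon and run count trade precision for time; on
  small graphs the influence vector is heavily tied at low $\beta$, and
  tau-a's tied-pair handling then compresses all correlations toward
  zero.
* The epidemic threshold $\beta_{th} = \langle k \rangle /
  (\langle k^2 \rangle - \langle k \rangle)$ is the degree-based
  mean-field estimate; on small or highly clustered graphs it is a rough
  guide, and it is reported for orientation only.
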