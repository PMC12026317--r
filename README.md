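# ledgm

Identification of influential spreader nodes in undirected networks with
the **local effective distance-integrated gravity model** (LEDGM), for
network scientists and systems biologists who need node-importance
rankings that track actual spreading dynamics rather than raw degree.

Gravity-model centralities score a node by summed pairwise attraction,
mass × mass / distance². LEDGM's mass is the *propagation capability*

    sp_i = exp(-C_i) * (k_i / kmax + ks_i / ksmax)

(degree `k`, k-shell index `ks`, local clustering `C`), and its distance
is the asymmetric *effective distance*: one hop from node `i` costs
`D_{j|i} = 1 + log2(k_i)`, multi-hop pairs take the shortest additive
effective path. The score of node `i` is

    IEDG_i = sum over j in phi_i of  sp_i * sp_j / D_{j|i}^2

where `phi_i` is the *effective-influence set* — the nodes within hop
distance `R = max(1, floor(diameter / 2))` of `i` — so effective
distances are computed only where they matter. The unrestricted all-pairs
variant (`ledgm_unrestricted()`) is included to quantify exactly what the
truncation changes.

Also provided: the comparator centralities (degree, betweenness,
closeness, k-shell, plain/generalized/effective-distance gravity models),
a discrete-time susceptible–infected simulator as the spreading-power
benchmark, Kendall tau-a ranking evaluation, seeded Erdős–Rényi
generators, edge-list/adjacency readers and writers, and a CLI.

## Worked example

The bundled seven-node network (`figure1_network()`: node 1 a degree-6
hub, diameter 2, hence truncation radius 1) exercises the full pipeline:

```r
library(ledgm)
g <- figure1_network()

round(propagation_capability(g), 4)
#>      1      2      3      4      5      6      7
#> 1.4331 0.4905 0.4905 0.7701 1.0109 0.7701 0.4905

influence_sets(g)$sets[["2"]]       # phi_2: nodes within 1 hop of node 2
#> [1] "1" "5"
direct_effective_length(g, "2", "1")  # 1 - log2(1/2)
#> [1] 2

round(ledgm(g)$scores, 4)
#>      1      2      3      4      5      6      7
#> 0.4485 0.2997 0.2997 0.3704 0.3577 0.3105 0.2702

rank_nodes(ledgm(g), k = 3)
#>   rank node     score
#> 1    1    1 0.4485476
#> 2    2    4 0.3704323
#> 3    3    5 0.3576509
```

The hub's mass (1.4331) combines its maximal degree and 2-shell position,
discounted by its clustering of 1/3; node 2 scores 0.2997, the sum of its
attractions to nodes 1 (0.1757) and 5 (0.1240) across effective distance 2.
The restricted model evaluates 22 source–target distance pairs here versus
42 for the all-pairs variant.

The fixture itself is reproduced from first principles:
`reconstruct_figure1_by_search()` exhaustively enumerates the 2^15
candidate topologies consistent with the hub's degree and filters by the
published structural constraints and score rows; exactly one graph
survives.

## Command line

```sh
exec/ledgm rank     --input net.edges --method ledgm --top 10
exec/ledgm simulate --input net.edges --beta 0.2 --steps 10 --runs 100 --top 10 --seed 1
exec/ledgm evaluate --input net.edges --methods dc,bc,cc,gm,edgm,ggm,ledgm --beta-grid 0.1,0.2,0.3 --seed 1
exec/ledgm generate --nodes 1000 --prob 0.01 --seed 1 --output er.edges
```

Outputs are CSV with a commented header that records the fully resolved
configuration (defaults and seed included), so every table is
regenerable from its own header.

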