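# superspreadr

Selecting k seed nodes that maximise spread on a network fails in a
characteristic way when the network has community structure: the top-k
nodes of any centrality ranking crowd into a few dense communities and
their influence overlaps. `superspreadr` implements a community-aware
top-k strategy for identifying multiple influential spreaders (for
information diffusion or targeted immunization), together with the
simulation and evaluation machinery needed to study it:

* **Super-node aggregation** — one (and only one) iteration of the
  Louvain modularity procedure, yielding many small communities
  ("super nodes") rather than a coarse hierarchy.
* **Sweep selection** — super nodes are visited in decreasing size
  order through a size-ordered index; each contributes at most one
  spreader: its highest-centrality member with no edge into any super
  node that already holds a spreader. The whole selection runs in
  O(m + n + (k + l) log l) for l super nodes.
* **Centrality indices** — degree, k-core (coreness), and ClusterRank
  (undirected adaptation, `10^(-c_u) * sum(k_v + 1)` over neighbours).
* **Benchmarks** — plain top-k (`select_influential`), the unconnected
  top-k greedy walk (`select_disperse`), and a bond-percolation
  k-medoid comparator (`estimate_transfer_matrix` + `select_kmedoid`).
* **SIR contact process** — discrete-time SIR in which each infected
  node contacts one uniformly random neighbour per step (transmission
  probability μ, recovery probability β, effective spreading rate
  λ = μ/β); `influence_scope()` averages the final ever-infected
  fraction over replicates.
* **Metrics & experiments** — growth ratio
  (p_ours − p_other)/p_other, coverage ratio (fraction of super nodes
  containing a seed), and `run_experiment()` sweeping seed fractions
  and methods with full seed-replay determinism.
* **Synthetic networks** — a self-contained LFR-style generator
  (power-law degrees and community sizes, tunable mixing), planted
  clique fixtures, and a 10-node toy network that walks through the
  selection rule.

Graphs are igraph objects; plain whitespace-separated edge lists are
read with `read_edge_list()`, and node ids are preserved verbatim.

## A worked example

```r
library(superspreadr)

net <- generate_lfr(n = 2000, seed = 1)      # LFR-style benchmark graph
p   <- louvain_one_pass(net$graph)           # one-pass super nodes
#> supernode_partition: 146 super nodes over 2000 nodes

sc    <- degree_centrality(net$graph)
seeds <- select_supernode(net$graph, p, sc, k = 30)
top   <- select_influential(net$graph, sc, 30)

coverage_ratio(seeds, p)                     # 0.205  (30 seeds, 30 super nodes)
coverage_ratio(top, p)                       # 0.041  (top-30 crowd together)

pars <- auto_sir_params(net$graph, lam = 1.5, runs = 200, seed = 1)
a <- influence_scope(net$graph, seeds, pars)
b <- influence_scope(net$graph, top, pars)
a$influence_scope                            # 0.134
b$influence_scope                            # 0.084
growth_ratio(a$influence_scope, b$influence_scope)
#> 0.597
```

The community-aware seeds land in 30 distinct super nodes where the
plain top-30 reach only 6, and the resulting epidemic reaches ~60% more
of the network under identical SIR settings (β = 1/⟨k⟩, λ = 1.5,
paired replicate seeds).

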